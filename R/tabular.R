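# Clinical/PET tabular encoding (D1) and design-matrix assembly.

#' Encode the clinical table into the 14-column D1 matrix
#'
#' Dichotomizes gender, TNM8 stage group (I-II vs III-IV), histologic grade
#' (low/moderate vs high) and Charlson group (0 vs 1-6), one-hot encodes
#' the four tumor sites, and appends the three standard PET parameters.
#' Rows with missing values are rejected (no imputation) and reported via
#' the `rejected` attribute.
#'
#' @param clinical data frame with columns `age`, `gender`, `smoking`,
#'   `tumor_site`, `stage_group`, `hpv_related`, `histologic_grade_group`,
#'   `charlson_group`, `suv_peak`, `mtv`, `tlg` (and optionally
#'   `patient_id` for row names).
#' @return numeric matrix with exactly 14 columns; attribute `rejected`
#'   lists dropped row indices.
#' @export
encode_d1 <- function(clinical) {
  needed <- c("age", "gender", "smoking", "tumor_site", "stage_group",
              "hpv_related", "histologic_grade_group", "charlson_group",
              "suv_peak", "mtv", "tlg")
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols) > 0)
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(clinical[, needed])
  rejected <- which(!ok)
  if (length(rejected) > 0)
    warning(length(rejected), " row(s) rejected for missing values: ",
            paste(rejected, collapse = ", "))
  cl <- clinical[ok, , drop = FALSE]
  sites <- c("oral_cavity", "oropharynx", "hypopharynx", "larynx")
  site <- gsub(" ", "_", tolower(cl$tumor_site))
  if (!all(site %in% sites))
    stop("unknown tumor_site value(s): ",
         paste(setdiff(site, sites), collapse = ", "))
  m <- cbind(
    age = as.numeric(cl$age),
    gender_male = as.numeric(cl$gender %in% c("male", "M", 1)),
    smoking_pack_years = as.numeric(cl$smoking),
    site_oral_cavity = as.numeric(site == "oral_cavity"),
    site_oropharynx = as.numeric(site == "oropharynx"),
    site_hypopharynx = as.numeric(site == "hypopharynx"),
    site_larynx = as.numeric(site == "larynx"),
    stage_iii_iv = as.numeric(cl$stage_group %in% c("III-IV", 1)),
    hpv_related = as.numeric(cl$hpv_related %in% c(1, "yes", TRUE)),
    grade_high = as.numeric(cl$histologic_grade_group %in% c("high", 1)),
    charlson_1_6 = as.numeric(cl$charlson_group %in% c("1-6", 1)),
    suv_peak = as.numeric(cl$suv_peak),
    mtv = as.numeric(cl$mtv),
    tlg = as.numeric(cl$tlg))
  if (!is.null(cl$patient_id)) rownames(m) <- cl$patient_id
  attr(m, "rejected") <- rejected
  m
}

#' D1 matrix for a phantom cohort
#'
#' Computes the standard PET parameters per patient and encodes the
#' clinical table.
#'
#' @param cohort a `phantom_cohort`.
#' @return 14-column D1 matrix.
#' @export
d1_matrix <- function(cohort) {
  pp <- t(vapply(cohort$patients, function(p) {
    v <- pet_params(p$pet, p$gtvp_mask, p$spacing[1])
    c(suv_peak = v$suv_peak, mtv = v$mtv, tlg = v$tlg)
  }, numeric(3)))
  encode_d1(cbind(cohort$clinical, as.data.frame(pp)))
}

#' Standardize continuous columns with train-only statistics
#'
#' z-score standardization (sample sd convention) whose mean/sd are
#' estimated on the training rows only and applied to all rows; binary
#' (0/1) columns are untouched and zero-sd columns are left unscaled and
#' flagged.
#'
#' @param m numeric matrix.
#' @param train_ids row indices (or row names) of the training subset.
#' @return list: `matrix` (standardized), `scaler` (center/scale/scaled),
#'   usable via [apply_scaler()].
#' @export
standardize_continuous <- function(m, train_ids = seq_len(nrow(m))) {
  tr <- m[train_ids, , drop = FALSE]
  if (nrow(tr) == 0L) stop("training subset is empty")
  scaler <- scale_fit(tr, binary_untouched = TRUE)
  list(matrix = scale_apply(m, scaler), scaler = scaler)
}

#' Apply a stored scaler to new rows
#'
#' @param m numeric matrix with the scaler's columns.
#' @param scaler the `scaler` element of [standardize_continuous()].
#' @return standardized matrix.
#' @export
apply_scaler <- function(m, scaler) scale_apply(m, scaler)

#' Assemble a design matrix from D1/D2 and a feature selection
#'
#' @param d1 clinical matrix (may be `NULL` when `dataset = "D2"`).
#' @param d2 radiomics matrix (may be `NULL` when `dataset = "D1"`).
#' @param dataset `"D1"`, `"D2"` or `"D1+D2"`.
#' @param selection optional character vector of feature names (e.g. a
#'   RENT frequency subset); an empty selection is an error, as are names
#'   absent from the assembled matrix.
#' @return design matrix restricted to the selection.
#' @export
assemble_inputs <- function(d1 = NULL, d2 = NULL,
                            dataset = c("D1", "D2", "D1+D2"),
                            selection = NULL) {
  dataset <- match.arg(dataset)
  m <- switch(dataset,
    "D1" = d1,
    "D2" = d2,
    "D1+D2" = {
      stopifnot(identical(rownames(d1), rownames(d2)))
      cbind(d1, d2)
    })
  if (is.null(m)) stop("required input block missing for dataset ", dataset)
  if (!is.null(selection)) {
    if (length(selection) == 0L)
      stop("empty feature selection; refusing to build an empty design matrix")
    absent <- setdiff(selection, colnames(m))
    if (length(absent) > 0)
      stop("selected features absent from the input: ",
           paste(absent, collapse = ", "))
    m <- m[, selection, drop = FALSE]
  }
  m
}
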