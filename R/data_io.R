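#' Construct a test-accuracy dataset
#'
#' Validates and assembles per-study 2x2 accuracy counts into the container
#' used by all meta-analysis functions in the package. Each study contributes
#' the number of true positives `r11` out of `n1` diseased (outcome-positive)
#' patients, the number of true negatives `r00` out of `n0` non-diseased
#' patients, and a study design label.
#'
#' Derived quantities (observed sensitivity `r11/n1`, specificity `r00/n0`,
#' prevalence `n1/(n1+n0)`, test-positive and test-negative totals) are
#' available via [study_measures()]. Observed prevalence is not an unbiased
#' estimate of outcome risk in case-control studies; such studies are
#' accepted but flagged with a warning and excluded from prevalence-based
#' analyses downstream.
#'
#' @param studies data.frame with columns `study_id`, `r11`, `n1`, `r00`,
#'   `n0` and optionally `design` (one of `"cohort"`, `"case_control"`,
#'   `"unknown"`; defaults to `"cohort"`).
#' @param name optional dataset label.
#' @return An object of class `acc_dataset` (a validated data.frame).
#' @examples
#' d <- acc_dataset(data.frame(study_id = c("a", "b"),
#'                             r11 = c(8, 15), n1 = c(10, 20),
#'                             r00 = c(18, 30), n0 = c(20, 35)))
#' study_measures(d)
#' @export
acc_dataset <- function(studies, name = "dataset") {
  req <- c("study_id", "r11", "n1", "r00", "n0")
  miss <- setdiff(req, names(studies))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"design" %in% names(studies)) studies$design <- "cohort"
  studies$design <- match.arg(as.character(studies$design),
                              c("cohort", "case_control", "unknown"),
                              several.ok = TRUE)
  studies$study_id <- as.character(studies$study_id)
  if (anyDuplicated(studies$study_id))
    stop("duplicate study_id: ",
         paste(unique(studies$study_id[duplicated(studies$study_id)]),
               collapse = ", "))
  for (cc in c("r11", "n1", "r00", "n0")) {
    x <- studies[[cc]]
    bad <- !is.finite(x) | x < 0 | x != round(x)
    if (any(bad))
      stop("invalid count in column '", cc, "' for study ",
           paste(studies$study_id[bad], collapse = ", "))
  }
  bad <- studies$r11 > studies$n1
  if (any(bad))
    stop("r11 > n1 for study ", paste(studies$study_id[bad], collapse = ", "))
  bad <- studies$r00 > studies$n0
  if (any(bad))
    stop("r00 > n0 for study ", paste(studies$study_id[bad], collapse = ", "))
  bad <- studies$n1 + studies$n0 == 0
  if (any(bad))
    stop("empty study ", paste(studies$study_id[bad], collapse = ", "))
  if (any(studies$design == "case_control"))
    warning("case_control studies present: their observed prevalence is ",
            "not interpretable and they are excluded from prevalence-based ",
            "analyses")
  out <- studies[, c("study_id", "r11", "n1", "r00", "n0", "design")]
  rownames(out) <- NULL
  attr(out, "name") <- name
  class(out) <- c("acc_dataset", "data.frame")
  out
}

#' Derived per-study accuracy measures
#'
#' @param data an [acc_dataset()].
#' @return data.frame with observed sensitivity, specificity, prevalence,
#'   total size `N`, and test-positive/negative totals per study.
#' @export
study_measures <- function(data) {
  stopifnot(inherits(data, "acc_dataset"))
  data.frame(
    study_id = data$study_id,
    sens_obs = data$r11 / data$n1,
    spec_obs = data$r00 / data$n0,
    N = data$n1 + data$n0,
    prevalence_obs = data$n1 / (data$n1 + data$n0),
    test_pos = data$r11 + (data$n0 - data$r00),
    test_neg = data$r00 + (data$n1 - data$r11),
    design = data$design,
    stringsAsFactors = FALSE
  )
}

#' @export
print.acc_dataset <- function(x, ...) {
  cat("Test accuracy dataset '", attr(x, "name"), "': ",
      nrow(x), " studies, N = ", sum(x$n1 + x$n0), "\n\n", sep = "")
  m <- study_measures(x)
  df <- data.frame(x[, c("study_id", "r11", "n1", "r00", "n0")],
                   sens = round(m$sens_obs, 2), spec = round(m$spec_obs, 2),
                   prev = round(m$prevalence_obs, 2), design = x$design)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

default_dialect <- c(study_id = "study_id", r11 = "r11", n1 = "n1",
                     r00 = "r00", n0 = "n0", design = "design")

#' Read per-study accuracy counts from CSV
#'
#' Reads a UTF-8 CSV with one row per study. There is no standard file
#' format for 2x2 meta-analysis data, so the column names are configurable
#' through `dialect`, a named character vector mapping the canonical names
#' (`study_id`, `r11`, `n1`, `r00`, `n0`, `design`) to the names used in
#' the file. `design` is optional and defaults to `"cohort"`.
#'
#' @param path CSV file path.
#' @param dialect named character vector overriding column names, e.g.
#'   `c(r11 = "TP", n1 = "n_diseased")`.
#' @param name dataset label; defaults to the file name.
#' @return An [acc_dataset()]; row order is preserved.
#' @export
read_studies_csv <- function(path, dialect = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dia <- default_dialect
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- dia[c("study_id", "r11", "n1", "r00", "n0")]
  miss <- setdiff(unname(need), names(df))
  if (length(miss))
    stop("column(s) not found in ", path, ": ", paste(miss, collapse = ", "),
         " (adjust 'dialect')")
  out <- data.frame(study_id = df[[dia["study_id"]]],
                    r11 = df[[dia["r11"]]], n1 = df[[dia["n1"]]],
                    r00 = df[[dia["r00"]]], n0 = df[[dia["n0"]]])
  if (dia["design"] %in% names(df)) out$design <- df[[dia["design"]]]
  acc_dataset(out, name = if (is.null(name)) basename(path) else name)
}

#' Write a dataset back to CSV
#'
#' Emits the same dialect [read_studies_csv()] reads, so a write/read
#' round trip reproduces the counts exactly.
#'
#' @inheritParams read_studies_csv
#' @param data an [acc_dataset()].
#' @export
write_studies_csv <- function(data, path, dialect = NULL) {
  stopifnot(inherits(data, "acc_dataset"))
  dia <- default_dialect
  if (!is.null(dialect)) dia[names(dialect)] <- dialect
  df <- as.data.frame(data)
  names(df) <- dia[names(df)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Packaged example datasets
#'
#' Three published meta-analysis datasets ship with the package as plain
#' CSV files:
#' \describe{
#'   \item{`temperature`}{11 studies (2323 children) of infrared ear
#'     thermometry at a 38 degC threshold against rectal temperature for
#'     diagnosing fever.}
#'   \item{`pth_0_20min`}{5 cohort studies of a >65\% drop in parathyroid
#'     hormone, measured 0-20 min post-thyroidectomy, for predicting
#'     hypocalcaemia within 48 h.}
#'   \item{`pth_1_2h`}{the same test measured 1-2 h post-surgery.}
#' }
#' All are cohort/cross-sectional designs, so their observed prevalences
#' are usable in prevalence meta-analysis and cross-validation.
#'
#' @param name fixture name.
#' @return An [acc_dataset()].
#' @examples
#' load_fixture("temperature")
#' @export
load_fixture <- function(name = c("temperature", "pth_1_2h", "pth_0_20min")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "accmeta",
                      mustWork = TRUE)
  read_studies_csv(path, name = name)
}
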