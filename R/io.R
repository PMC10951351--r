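#' Write a grouped cohort with its dose-vector realizations as CSV
#'
#' One row per dose group with columns `group`, `cases`, `person_years`
#' and `dose_rep_0001` ... `dose_rep_m`, so estimators can be run on
#' externally supplied grouped data.
#'
#' @param cohort a [grouped_cohort()].
#' @param doses a [dose_vector_set()] (or `m x G` matrix).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_grouped_data <- function(cohort, doses, path) {
  v <- if (inherits(doses, "doserr_dose_set")) doses$vectors else
    as.matrix(doses)
  if (ncol(v) != length(cohort$cases)) stop("dose/cohort group mismatch")
  dmat <- t(v)  # G x m
  colnames(dmat) <- sprintf("dose_rep_%04d", seq_len(ncol(dmat)))
  df <- data.frame(group = seq_along(cohort$cases),
                   cases = cohort$cases,
                   person_years = cohort$person_years)
  write.csv(cbind(df, dmat), path, row.names = FALSE)
  invisible(path)
}

#' Read a grouped cohort and dose-vector realizations from CSV
#'
#' Inverse of [write_grouped_data()].
#'
#' @param path CSV path.
#' @return list with `cohort` (a [grouped_cohort()]) and `doses` (a
#'   [dose_vector_set()]).
#' @export
read_grouped_data <- function(path) {
  df <- read.csv(path)
  need <- c("group", "cases", "person_years")
  if (!all(need %in% names(df))) {
    stop("CSV must contain columns: ", paste(need, collapse = ", "))
  }
  dcols <- grep("^dose_rep_", names(df), value = TRUE)
  if (!length(dcols)) stop("no dose_rep_* columns found")
  df <- df[order(df$group), ]
  list(cohort = grouped_cohort(df$cases, df$person_years),
       doses = dose_vector_set(t(as.matrix(df[, dcols, drop = FALSE]))))
}
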