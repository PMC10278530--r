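#' Contingency table container
#'
#' @param counts r x c matrix of nonnegative integer counts (r, c >= 2).
#' @param row_labels,col_labels Optional dimension labels.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop2("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be nonnegative integers")
  if (sum(counts) <= 0) stop2("table total must be positive")
  storage.mode(counts) <- "integer"
  rownames(counts) <- row_labels
  colnames(counts) <- col_labels
  structure(list(counts = counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> n =", sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' Published baseline association tables
#'
#' The 2x2 and 4x2 count tables of the 114-patient cohort's baseline
#' characteristics, cross-tabulated against the inner-tumor and ITF TSR
#' groups.  Rows are characteristic levels in printed order; columns are
#' `tumor_high`, `tumor_low`.  Keys are `<characteristic>_<zone>` with
#' zone `inner` or `itf` (e.g. `"pni_inner"`, `"poi_itf"`).
#'
#' @return Named list of [contingency_table] objects (grand total 114
#'   each).
#' @export
table1_fixtures <- function() {
  cols <- c("tumor_high", "tumor_low")
  tab <- function(rows, m) {
    contingency_table(matrix(m, nrow = length(rows), byrow = TRUE),
                      row_labels = rows, col_labels = cols)
  }
  list(
    sex_inner   = tab(c("male", "female"),        c(51, 18, 34, 11)),
    sex_itf     = tab(c("male", "female"),        c(40, 29, 23, 22)),
    age_inner   = tab(c("<60", ">=60"),           c(35, 9, 50, 20)),
    age_itf     = tab(c("<60", ">=60"),           c(26, 18, 37, 33)),
    stage_inner = tab(c("I", "II", "III", "IV"),
                      c(7, 1, 17, 7, 16, 4, 45, 17)),
    stage_itf   = tab(c("I", "II", "III", "IV"),
                      c(5, 3, 13, 11, 12, 8, 33, 29)),
    differentiation_inner = tab(c("well", "moderate-poor"),
                                c(67, 18, 18, 11)),
    differentiation_itf   = tab(c("well", "moderate-poor"),
                                c(47, 38, 16, 13)),
    smoking_inner = tab(c("no", "yes"),           c(50, 18, 35, 11)),
    smoking_itf   = tab(c("no", "yes"),           c(37, 31, 26, 20)),
    poi_inner   = tab(c("1-3", "4-5"),            c(53, 11, 32, 18)),
    poi_itf     = tab(c("1-3", "4-5"),            c(44, 20, 19, 31)),
    wpoi_inner  = tab(c("1-3", "4-5"),            c(24, 6, 61, 23)),
    wpoi_itf    = tab(c("1-3", "4-5"),            c(22, 8, 41, 43)),
    doi_inner   = tab(c("<5mm", ">=5mm"),         c(28, 6, 57, 23)),
    doi_itf     = tab(c("<5mm", ">=5mm"),         c(22, 12, 41, 39)),
    pni_inner   = tab(c("no", "yes"),             c(68, 12, 17, 17)),
    pni_itf     = tab(c("no", "yes"),             c(53, 27, 10, 24)))
}
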