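tlx_dimensions <- function() {
  c("mental", "physical", "temporal", "performance", "effort", "frustration")
}

#' NASA-TLX record
#'
#' One respondent's NASA Task Load Index answers: six subscale scores on
#' the 0-100 scale and the six pairwise-comparison win tallies (15 pairs in
#' total, so the tallies sum to 15). Note that the performance subscale is
#' oriented so that higher means a worse subjective rating.
#'
#' @param scores numeric vector of 6 scores in `[0, 100]`, in the order
#'   mental, physical, temporal, performance, effort, frustration (a named
#'   vector in any order is matched by name).
#' @param tallies non-negative integer wins per dimension, summing to 15.
#' @return object of class `tlx_record` with the weighted workload in
#'   `$wwl`.
#' @export
tlx_record <- function(scores, tallies) {
  dims <- tlx_dimensions()
  if (!is.null(names(scores))) scores <- scores[dims]
  if (!is.null(names(tallies))) tallies <- tallies[dims]
  scores <- as.numeric(scores); tallies <- as.numeric(tallies)
  if (length(scores) != 6L || anyNA(scores) ||
      any(scores < 0 | scores > 100))
    stop("scores must be 6 values in [0, 100]", call. = FALSE)
  if (length(tallies) != 6L || anyNA(tallies) || any(tallies < 0) ||
      any(tallies != round(tallies)))
    stop("tallies must be 6 non-negative integers", call. = FALSE)
  if (sum(tallies) != 15)
    stop("pairwise-comparison tallies must sum to 15 (got ", sum(tallies),
         ")", call. = FALSE)
  rec <- structure(list(scores = stats::setNames(scores, dims),
                        tallies = stats::setNames(as.integer(tallies), dims)),
                   class = "tlx_record")
  rec$wwl <- weighted_workload(rec)
  rec
}

#' NASA-TLX weighted workload
#'
#' `WWL = sum(tally_i * score_i) / 15`: the pairwise-comparison-weighted
#' mean of the six subscale scores. Always lies between the smallest and
#' largest score, hence in `[0, 100]`.
#'
#' @param rec a [tlx_record()].
#' @return the WWL value.
#' @export
weighted_workload <- function(rec) {
  stopifnot(inherits(rec, "tlx_record"))
  sum(rec$tallies * rec$scores) / 15
}

#' @export
print.tlx_record <- function(x, ...) {
  cat(sprintf("<tlx_record> WWL = %.2f\n", x$wwl))
  for (d in tlx_dimensions())
    cat(sprintf("  %-12s score %5.1f  weight %d/15\n", d, x$scores[[d]],
                x$tallies[[d]]))
  invisible(x)
}

#' Read NASA-TLX responses from CSV
#'
#' Expected columns: `subject`, `paradigm`, one score column per dimension
#' (`mental`, `physical`, `temporal`, `performance`, `effort`,
#' `frustration`) and 15 pairwise-choice columns `pair1`..`pair15`, each
#' holding the dimension name that won the comparison.
#'
#' @param path CSV path.
#' @return data.frame with one row per respondent: subject, paradigm, the
#'   six scores, the six tallies and `wwl`.
#' @export
read_tlx_csv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  dims <- tlx_dimensions()
  pair_cols <- grep("^pair", names(df), value = TRUE)
  if (length(pair_cols) != 15L)
    stop("expected 15 pairwise-choice columns (pair1..pair15)", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    wins <- unlist(df[i, pair_cols], use.names = FALSE)
    bad <- setdiff(unique(wins), dims)
    if (length(bad) > 0L)
      stop("unknown dimension in pairwise choices: ",
           paste(bad, collapse = ", "), call. = FALSE)
    tallies <- vapply(dims, function(d) sum(wins == d), 0L)
    rec <- tlx_record(unlist(df[i, dims]), tallies)
    data.frame(subject = df$subject[i], paradigm = df$paradigm[i],
               t(rec$scores), t(stats::setNames(as.integer(rec$tallies),
                                                paste0("w_", dims))),
               wwl = rec$wwl, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
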