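#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))
invlogit <- stats::plogis

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' Used so that each simulated column (and each pipeline stage) draws from its
#' own RNG substream: adding columns never perturbs the draws of earlier ones.
#' @noRd
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))) * 131)
  as.integer((abs(seed) * 7919 + h) %% 2147483587L)
}

#' Evaluate an expression under a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Weighted mean and variance (frequency-normalised)
#' @noRd
wmean <- function(x, w) sum(w * x) / sum(w)

wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Kish effective sample size for a weight vector
#' @noRd
kish_neff <- function(w) sum(w)^2 / sum(w^2)

#' Stratified k-fold assignment
#'
#' Returns an integer fold id per observation; folds are balanced within each
#' outcome class so every fold sees both classes whenever possible.
#' @noRd
stratified_folds <- function(outcome, k, seed) {
  fold <- integer(length(outcome))
  with_seed(seed, {
    for (cls in unique(outcome)) {
      idx <- which(outcome == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

check_binary_outcome <- function(y, what = "outcome") {
  if (anyNA(y)) stop(what, " contains missing values", call. = FALSE)
  u <- unique(y)
  if (!all(u %in% c(0, 1))) stop(what, " must be coded 0/1", call. = FALSE)
  if (length(u) < 2L) stop(what, " has a single class; both classes required", call. = FALSE)
  invisible(TRUE)
}

#' Write a data.frame as TSV with a metadata comment header
#' @noRd
write_tsv_meta <- function(x, path, meta = list()) {
  meta <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 package = as.character(utils::packageVersion("polysocial"))),
            meta)
  hdr <- paste0("# ", names(meta), "=", vapply(meta, as.character, ""), collapse = "\n")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
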