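#' Probability of observing a given k-mer in a random sequence
#'
#' For a fixed word K of length `k` and a random sequence of length `n`
#' over an alphabet of size `sigma`, the chance that K occurs at least once
#' is approximately `1 - (1 - sigma^-k)^n` (positions treated as
#' independent draws).
#'
#' @param k word length (>= 1).
#' @param n sequence length (>= 1).
#' @param sigma alphabet size, 4 for DNA.
#' @return probability in \[0, 1\]; vectorized over `k` and `n`.
#' @export
random_kmer_probability <- function(k, n, sigma = 4) {
  stopifnot(all(k >= 1), all(n >= 1), sigma >= 2)
  1 - (1 - sigma^(-k))^n
}

#' Choose a k-mer length from the document size
#'
#' Inverts [random_kmer_probability()]: given the desired probability `q`
#' of seeing a random k-mer in a document of `n` residues, returns
#' `ceiling(log_sigma(n (1 - q) / q))`, floored at 1.  With the default
#' `q = 0.01` this gives k = 9 for ~1000-bp loci and k = 8 for the 300-420
#' bp range typical of Sanger-era population data.  For very long
#' documents (megabase pooled reads) a fixed k around 20 is the usual
#' choice instead.
#'
#' @param n document length in residues (>= 2); vectorized.
#' @param q target probability of a random k-mer match, in (0, 1).
#' @param sigma alphabet size.
#' @return integer k-mer length(s).
#' @export
estimate_k <- function(n, q = 0.01, sigma = 4) {
  stopifnot(all(n >= 2), q > 0, q < 1, sigma >= 2)
  pmax(1L, as.integer(ceiling(log(n * (1 - q) / q) / log(sigma))))
}

#' Pick the k-mer length for a locus
#'
#' In `"estimate"` mode, k is computed per document with [estimate_k()]
#' and aggregated across documents; the default aggregate is the maximum,
#' which is conservative against chance matches in the longest document.
#' In `"fixed"` mode the supplied `k` is returned as-is; a vector of
#' lengths selects a mixture of k-mer sizes in [decompose()].
#'
#' @param locus a [locus_data()] object.
#' @param mode `"estimate"` or `"fixed"`.
#' @param k fixed k-mer length(s), used when `mode = "fixed"`.
#' @param q,sigma passed to [estimate_k()].
#' @param aggregate how to combine per-document estimates: `"max"`,
#'   `"median"` or `"mode"` (most frequent, smallest on ties).
#' @return integer vector of k-mer length(s) (length 1 unless a fixed
#'   mixture is requested).
#' @export
locus_k <- function(locus, mode = c("estimate", "fixed"), k = NULL,
                    q = 0.01, sigma = 4,
                    aggregate = c("max", "median", "mode")) {
  stopifnot(inherits(locus, "locus_data"))
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(k)) stop("mode 'fixed' needs k")
    return(as.integer(k))
  }
  aggregate <- match.arg(aggregate)
  ks <- estimate_k(nchar(locus$sequences), q = q, sigma = sigma)
  switch(aggregate,
         max = max(ks),
         median = as.integer(round(median(ks))),
         mode = {
           tab <- table(ks)
           as.integer(names(tab)[which.max(tab)])
         })
}

.tokenize_one <- function(seq, k) {
  L <- nchar(seq)
  nwin <- L %/% k
  if (nwin == 0L) return(character(0))
  starts <- seq.int(1L, by = k, length.out = nwin)
  substring(seq, starts, starts + k - 1L)
}

.drop_gap_columns <- function(sequences) {
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  keep <- colSums(mat == "-") == 0L
  apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
}

#' Decompose a locus into non-overlapping k-mers
#'
#' Each document is cut into consecutive windows of length `k` starting at
#' its first position; a trailing remainder shorter than `k` is discarded.
#' Overlapping windows are deliberately not used.
#'
#' Gap handling (`gap_mode`):
#' \describe{
#'   \item{`keep_all`}{"-" is an ordinary symbol; gap-bearing k-mers carry
#'     indel information (sensible for aligned loci).}
#'   \item{`drop_gap_kmers`}{windows are cut first, then any window
#'     containing "-" is removed; surviving windows stay anchored to
#'     alignment coordinates.}
#'   \item{`strip_gaps`}{all "-" are removed before cutting, i.e. the
#'     sequences are treated as unaligned.}
#'   \item{`drop_gap_columns`}{alignment columns holding a gap in any row
#'     are removed before cutting (aligned loci only).}
#' }
#' With `drop_ambiguous = TRUE`, windows containing "N" or "?" are removed
#' after cutting.  All other IUPAC codes are kept verbatim.
#'
#' @param locus a [locus_data()] object.
#' @param k k-mer length(s); `NULL` estimates it with [locus_k()].  A
#'   vector pools windows of several lengths.
#' @param gap_mode gap treatment, see Details.
#' @param drop_ambiguous drop windows containing "N" or "?".
#' @param q,sigma passed to [locus_k()] when `k` is estimated.
#' @return an object of class `kmer_corpus`: a list with `locus_id`,
#'   `docs` (named list of k-mer character vectors, one per document) and
#'   `k` (lengths used).
#' @export
decompose <- function(locus, k = NULL,
                      gap_mode = c("keep_all", "drop_gap_kmers",
                                   "strip_gaps", "drop_gap_columns"),
                      drop_ambiguous = FALSE, q = 0.01, sigma = 4) {
  stopifnot(inherits(locus, "locus_data"))
  gap_mode <- match.arg(gap_mode)
  seqs <- locus$sequences
  if (gap_mode == "strip_gaps")
    seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (gap_mode == "drop_gap_columns") {
    if (!locus$aligned)
      stop("drop_gap_columns requires an aligned locus")
    seqs <- .drop_gap_columns(seqs)
    names(seqs) <- locus$labels
  }
  if (is.null(k)) {
    # estimate from the documents as they will be tokenized
    tmp <- seqs
    tmp[!nzchar(tmp)] <- "NN"
    names(tmp) <- locus$labels
    k <- locus_k(locus_data(tmp, locus_id = locus$locus_id,
                            aligned = FALSE), q = q, sigma = sigma)
  }
  k <- as.integer(k)
  docs <- lapply(seqs, function(s) {
    toks <- unlist(lapply(k, .tokenize_one, seq = s), use.names = FALSE)
    if (gap_mode == "drop_gap_kmers")
      toks <- toks[!grepl("-", toks, fixed = TRUE)]
    if (drop_ambiguous)
      toks <- toks[!grepl("[N?]", toks)]
    toks
  })
  names(docs) <- locus$labels
  structure(list(locus_id = locus$locus_id, docs = docs, k = k),
            class = "kmer_corpus")
}

#' @export
print.kmer_corpus <- function(x, ...) {
  cat("<kmer_corpus> ", x$locus_id, ": ", length(x$docs),
      " documents, k = ", paste(x$k, collapse = "/"),
      ", tokens = ", sum(lengths(x$docs)), "\n", sep = "")
  invisible(x)
}
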