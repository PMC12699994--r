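#' Construct a locus data object
#'
#' A locus holds one DNA sequence per taxon ("document" in the topic-model
#' sense).  Labels must be unique; aligned loci must have equal-length
#' sequences.
#'
#' @param sequences named character vector of DNA sequences (upper case is
#'   enforced); names are the taxon/group labels.
#' @param locus_id identifier for the locus.
#' @param aligned logical; if `TRUE` the sequences are an alignment and
#'   must all have the same length.
#' @return an object of class `locus_data` with fields `locus_id`,
#'   `labels`, `sequences` and `aligned`.
#' @export
locus_data <- function(sequences, locus_id = "locus", aligned = FALSE) {
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("sequences must be a named character vector")
  if (length(sequences) < 2)
    stop("a locus needs at least 2 sequences, got ", length(sequences))
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicate sequence label(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(sequences)))
    stop("empty sequence for label(s): ",
         paste(labels[!nzchar(sequences)], collapse = ", "))
  sequences <- toupper(sequences)
  if (aligned && length(unique(nchar(sequences))) != 1L)
    stop("locus '", locus_id, "' marked aligned but sequence lengths differ")
  structure(list(locus_id = as.character(locus_id), labels = labels,
                 sequences = sequences, aligned = isTRUE(aligned)),
            class = "locus_data")
}

#' @export
print.locus_data <- function(x, ...) {
  cat("<locus_data> ", x$locus_id, ": ", length(x$labels), " sequences",
      if (x$aligned) paste0(", aligned width ", nchar(x$sequences[[1]])),
      "\n", sep = "")
  invisible(x)
}

#' Read one locus from a FASTA file
#'
#' Headers are parsed up to the first whitespace; sequences are uppercased.
#' Plain and gzip-compressed files are supported.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @param aligned logical, passed to [locus_data()].
#' @param locus_id locus identifier; defaults to the file name without
#'   extension.
#' @return a [locus_data()] object.
#' @export
read_locus_fasta <- function(path, aligned = FALSE, locus_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  recs <- seqinr::read.fasta(con, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- names(recs)
  if (length(seqs) < 2)
    stop("FASTA file ", path, " has fewer than 2 records")
  locus_data(seqs, locus_id = locus_id, aligned = aligned)
}

#' Write a locus to a FASTA file
#'
#' One record per document, sequence on a single line (round-trips exactly
#' through [read_locus_fasta()]).
#'
#' @param locus a [locus_data()] object.
#' @param path output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  stopifnot(inherits(locus, "locus_data"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", locus$labels, "\n", locus$sequences), con)
  invisible(path)
}

#' Bundle loci into a dataset
#'
#' The bundle fixes a canonical tip ordering (`group_order`, first
#' appearance across loci in locus order) that determines the row order of
#' the assembled character matrix.
#'
#' @param loci list of [locus_data()] objects.
#' @param group_order optional character vector fixing the tip order; every
#'   locus label must occur in it.
#' @return an object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(loci, group_order = NULL) {
  if (!length(loci)) stop("empty locus list")
  stopifnot(all(vapply(loci, inherits, logical(1), "locus_data")))
  seen <- unique(unlist(lapply(loci, `[[`, "labels")))
  if (is.null(group_order)) group_order <- seen
  missing <- setdiff(seen, group_order)
  if (length(missing))
    stop("labels not in group_order: ", paste(missing, collapse = ", "))
  ids <- vapply(loci, `[[`, character(1), "locus_id")
  names(loci) <- ids
  structure(list(loci = loci, group_order = group_order),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat("<dataset_bundle> ", length(x$loci), " loci, ",
      length(x$group_order), " groups\n", sep = "")
  invisible(x)
}

#' Read a directory of per-locus FASTA files
#'
#' One FASTA file per locus; lexicographic file order defines the locus
#' order.
#'
#' @param dir directory containing the files.
#' @param pattern regular expression selecting locus files.
#' @param aligned logical flag applied to every locus.
#' @param merge_prefix if non-`NULL`, [merge_by_prefix()] is applied with
#'   this prefix length to every locus.
#' @return a [dataset_bundle()].
#' @export
read_loci <- function(dir, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                      aligned = FALSE, merge_prefix = NULL) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no FASTA files matching '", pattern, "' in ", dir)
  loci <- lapply(files, read_locus_fasta, aligned = aligned)
  if (!is.null(merge_prefix))
    loci <- lapply(loci, merge_by_prefix, n = merge_prefix)
  dataset_bundle(loci)
}

#' Merge individuals into groups by label prefix
#'
#' Sequences whose labels share the same first `n` characters are
#' concatenated (in input order) into a single document labeled by the
#' shared prefix.  This pools the k-mer multisets of the group members,
#' the natural bag-of-words treatment for populations sampled with
#' several individuals.
#'
#' @param locus a [locus_data()] object.
#' @param n prefix length (>= 1).
#' @return a [locus_data()] with one document per prefix group.  The
#'   merged locus is never flagged aligned (concatenation breaks column
#'   correspondence unless every group has one member).
#' @export
merge_by_prefix <- function(locus, n) {
  stopifnot(inherits(locus, "locus_data"))
  n <- as.integer(n)
  if (n < 1) stop("prefix length n must be >= 1")
  if (all(nchar(locus$labels) < n))
    stop("prefix length ", n, " exceeds every label length")
  pref <- substr(locus$labels, 1L, n)
  groups <- unique(pref)
  merged <- vapply(groups, function(g)
    paste(locus$sequences[pref == g], collapse = ""), character(1))
  names(merged) <- groups
  sizes <- table(pref)[groups]
  aligned_ok <- locus$aligned && all(sizes == 1L)
  locus_data(merged, locus_id = locus$locus_id, aligned = aligned_ok)
}

#' Concatenate raw reads into pseudo-loci
#'
#' Raw (e.g. long-read) sequences are pooled in input order: every `chunk`
#' consecutive reads are concatenated into one sequence; a final partial
#' chunk is kept.  Concatenating 100,000 reads with `chunk = 1000` yields
#' 100 pseudo-loci.
#'
#' @param reads character vector of DNA sequences.
#' @param chunk number of reads per pseudo-locus (>= 1).
#' @return character vector of concatenated sequences.
#' @export
concatenate_reads <- function(reads, chunk) {
  if (!length(reads)) stop("empty read list")
  chunk <- as.integer(chunk)
  if (chunk < 1) stop("chunk must be >= 1")
  idx <- ceiling(seq_along(reads) / chunk)
  unname(vapply(split(reads, idx), paste, character(1), collapse = ""))
}

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} keeping branch lengths to at least 10
#' significant digits and internal node labels (bootstrap supports) intact.
#' `read_newick` reads one or more trees (one per line).
#'
#' @param path file path.
#' @return `read_newick`: a `phylo` or `multiPhylo` object; `write_newick`:
#'   the path, invisibly.
#' @export
read_newick <- function(path) {
  out <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick parse error in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(out)) stop("Newick parse error in ", path)
  out
}

#' @param tree a `phylo` object (or list of them).
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
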