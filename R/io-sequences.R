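#' Read an aligned FASTA file of mtDNA haplotype sequences
#'
#' Records must all have the same length (the file is consumed pre-aligned).
#' Sequences are uppercased; only A, C, G, T, N and the gap character "-"
#' are allowed. A population label can be parsed from the record id with a
#' regular expression.
#'
#' @param path FASTA file path.
#' @param pop_pattern regular expression with one capture group applied to
#'   each record id to extract the population label; ids that do not match
#'   get population "unknown". Default captures the prefix before the first
#'   underscore.
#' @return A \linkS4class{HaplotypeAlignment}.
#' @export
readFastaAlignment <- function(path, pop_pattern = "^([^_]+)_") {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  chars <- toupper(as.character(seqs))
  w <- nchar(chars)
  if (length(unique(w)) > 1) {
    bad <- names(seqs)[which(w != w[1])[1]]
    stop("unequal sequence lengths; offending record: ", bad)
  }
  letters <- unique(strsplit(paste(chars, collapse = ""), "")[[1]])
  disallowed <- setdiff(letters, c("A", "C", "G", "T", "N", "-"))
  if (length(disallowed))
    stop("disallowed character(s) in alignment: ",
         paste(disallowed, collapse = ", "))
  ids <- sub("\\s.*$", "", names(seqs))
  m <- regmatches(ids, regexec(pop_pattern, ids))
  pop <- vapply(m, function(x) if (length(x) >= 2) x[2] else "unknown", "")
  new("HaplotypeAlignment",
      seqs = Biostrings::DNAStringSet(stats::setNames(chars, ids)), pop = pop)
}

#' Construct a HaplotypeAlignment from character sequences
#'
#' @param sequences named character vector of equal-length aligned sequences.
#' @param pop population labels (recycled if length 1).
#' @return A \linkS4class{HaplotypeAlignment}.
#' @export
haplotypeAlignment <- function(sequences, pop) {
  if (length(pop) == 1L) pop <- rep(pop, length(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  new("HaplotypeAlignment",
      seqs = Biostrings::DNAStringSet(toupper(sequences)), pop = pop)
}

#' Collapse aligned sequences into haplotype counts per population
#'
#' Sites containing a gap ("-") or an ambiguous base ("N") in \emph{any}
#' sequence are excluded alignment-wide (complete deletion); the remaining
#' site strings are grouped by identity.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @return list with \code{counts} (integer matrix populations x haplotypes,
#'   haplotypes ordered by decreasing total count and labelled H1, H2, ...),
#'   \code{sequences} (the core site string of each haplotype) and
#'   \code{included_sites} (1-based positions retained).
#' @export
collapseHaplotypes <- function(aln) {
  stopifnot(is(aln, "HaplotypeAlignment"))
  if (!length(aln@seqs)) stop("empty alignment")
  mat <- do.call(rbind, strsplit(as.character(aln@seqs), ""))
  keep <- which(colSums(mat == "-" | mat == "N") == 0)
  if (!length(keep)) stop("complete deletion removed every site")
  core <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  haps <- names(sort(table(core), decreasing = TRUE))
  counts <- table(factor(aln@pop, levels = sort(unique(aln@pop))),
                  factor(core, levels = haps))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts),
                                   sprintf("H%d", seq_along(haps))))
  list(counts = counts,
       sequences = stats::setNames(haps, colnames(counts)),
       included_sites = keep)
}

#' Write an ultrametric clustering tree as Newick
#'
#' Leaf labels containing whitespace are single-quoted.
#'
#' @param tree an \code{ape::phylo} tree (e.g. from \link{upgmaTree}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  needsQuote <- grepl("\\s", lab)
  # ape rewrites blanks inside labels, so shield them with a sentinel and
  # restore after serialization
  shielded <- gsub(" ", "\x01", gsub("'", "''", lab), fixed = TRUE)
  tree$tip.label <- ifelse(needsQuote, paste0("'", shielded, "'"), lab)
  txt <- ape::write.tree(tree)
  txt <- gsub("\x01", " ", txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}
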