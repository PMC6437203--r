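#' Read a Genepop file into a GenotypeTable
#'
#' Dialect: first line is a title; locus names follow, either one per line
#' or comma-separated on one line; population blocks are introduced by a
#' line reading "Pop" (case-insensitive). Individual lines are
#' \code{id , g1 g2 ...} with 2- or 3-digit per-allele encoding
#' (auto-detected from genotype width: 4 characters = 2-digit alleles,
#' 6 characters = 3-digit). "0", "00" or "000" allele fields denote a
#' missing allele; a genotype with any missing allele is treated as missing.
#'
#' @param path path to a Genepop (.gen) file.
#' @param pop_names optional character vector of population names; by
#'   default each block is named after its last individual id (Genepop
#'   convention), de-duplicated.
#' @return A \linkS4class{GenotypeTable}.
#' @export
readGenepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("not a Genepop file (fewer than 3 lines)")
  isPop <- toupper(trimws(lines)) == "POP"
  firstPop <- which(isPop)[1]
  if (is.na(firstPop)) stop("no 'Pop' line found")
  locLines <- lines[2:(firstPop - 1)]
  loci <- trimws(unlist(strsplit(locLines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names before the first 'Pop' line")
  blocks <- split(which(!isPop & seq_along(lines) > firstPop),
                  cumsum(isPop)[!isPop & seq_along(lines) > firstPop])
  if (length(blocks) != sum(isPop))
    stop("empty Pop block (", sum(isPop) - length(blocks), " block(s) have",
         " no individuals)")
  ids <- character(); pop <- character(); rows <- list()
  digits <- NA_integer_
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    bl <- bl[nzchar(trimws(lines[bl]))]
    if (!length(bl)) stop("empty Pop block (block ", b, ")")
    blockIds <- character(length(bl))
    for (j in seq_along(bl)) {
      i <- bl[j]
      parts <- strsplit(lines[i], ",")[[1]]
      if (length(parts) < 2)
        stop("line ", i, ": expected 'id , genotypes'")
      id <- trimws(parts[1])
      gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
      if (length(gts) != length(loci))
        stop("line ", i, ": ", length(gts), " genotypes for ",
             length(loci), " loci")
      if (!all(grepl("^[0-9]+$", gts)))
        stop("line ", i, ": non-numeric allele field")
      w <- unique(nchar(gts))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop("line ", i, ": genotype fields must be uniformly 4 or 6 digits")
      d <- w / 2L
      if (is.na(digits)) digits <- d
      else if (digits != d)
        stop("line ", i, ": mixed 2- and 3-digit allele encodings")
      a1 <- as.integer(substr(gts, 1, d))
      a2 <- as.integer(substr(gts, d + 1, 2 * d))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      blockIds[j] <- id
      rows[[length(rows) + 1L]] <- cbind(a1, a2)
    }
    pname <- if (!is.null(pop_names)) pop_names[b] else blockIds[length(blockIds)]
    ids <- c(ids, blockIds)
    pop <- c(pop, rep(pname, length(bl)))
  }
  n <- length(ids)
  arr <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (i in seq_len(n)) arr[i, , ] <- rows[[i]]
  # distinct blocks must get distinct labels even if their names collide
  r <- rle(pop)
  r$values <- make.unique(r$values)
  pop <- inverse.rle(r)
  genotypeTable(ids, pop, arr, loci)
}

#' Write a GenotypeTable as a Genepop file
#'
#' @param gt a \linkS4class{GenotypeTable}.
#' @param path output path.
#' @param title title line (first line of the file).
#' @param digits per-allele digits (2 or 3); default 3, or 2 when all
#'   allele codes fit in two digits is still written as 3 for uniformity.
#' @return \code{path}, invisibly.
#' @export
writeGenepop <- function(gt, path, title = "HatcheryImpact export", digits = 3L) {
  stopifnot(is(gt, "GenotypeTable"), digits %in% c(2L, 3L))
  if (any(gt@alleles >= 10^digits, na.rm = TRUE))
    stop("allele codes too wide for ", digits, "-digit encoding")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(gt@loci, con)
  fmt <- paste0("%0", digits, "d")
  for (p in unique(gt@pop)) {
    writeLines("Pop", con)
    for (i in which(gt@pop == p)) {
      a <- gt@alleles[i, , , drop = TRUE]
      if (is.null(dim(a))) a <- matrix(a, ncol = 2)  # single locus
      g <- ifelse(is.na(a[, 1]),
                  paste0(sprintf(fmt, 0), sprintf(fmt, 0)),
                  paste0(sprintf(fmt, a[, 1]), sprintf(fmt, a[, 2])))
      writeLines(paste0(gt@ids[i], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
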