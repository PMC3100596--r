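#' Parse pipe-delimited tip labels
#'
#' Tips of gametolog trees and alignments are labelled
#' `species|gametolog|individual[|clone]`, e.g. `Ha|Y|m03|c2`. The gametolog
#' field must be one of `X`, `Y`, `autosomal`, `unknown`.
#'
#' @param labels character vector of tip labels.
#' @return `data.frame` with columns `label`, `species`, `gametolog`,
#'   `individual`, `clone` (`NA` when absent).
#' @export
parse_tip_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  n <- lengths(parts)
  bad <- n < 3L | n > 4L
  if (any(bad))
    stop("unparseable tip label: '", labels[bad][1],
         "' (expected species|gametolog|individual[|clone])")
  gam <- vapply(parts, `[[`, "", 2L)
  badg <- !gam %in% c("X", "Y", "autosomal", "unknown")
  if (any(badg))
    stop("unparseable tip label: '", labels[badg][1],
         "' (gametolog must be X, Y, autosomal or unknown)")
  data.frame(label = labels,
             species = vapply(parts, `[[`, "", 1L),
             gametolog = gam,
             individual = vapply(parts, `[[`, "", 3L),
             clone = vapply(parts, function(p)
               if (length(p) == 4L) p[[4]] else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' @rdname parse_tip_labels
#' @param species,gametolog,individual,clone components to render.
#' @export
make_tip_label <- function(species, gametolog, individual, clone = NULL) {
  base <- paste(species, gametolog, individual, sep = "|")
  if (is.null(clone)) base else {
    ifelse(is.na(clone), base, paste(base, clone, sep = "|"))
  }
}

#' Read/write labelled Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser that additionally validate
#' tip labels (see [parse_tip_labels]), require branch lengths, and preserve
#' internal-node support labels. Round trips are lossless to 10 significant
#' digits in branch lengths.
#'
#' @param path file path.
#' @return `read_newick`: an \pkg{ape} `phylo` whose tip labels parse as
#'   `species|gametolog|individual[|clone]`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (is.null(tr$edge.length)) stop("Newick tree lacks branch lengths: ", path)
  if (any(tr$edge.length < 0)) stop("negative branch length in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in ", path)
  parse_tip_labels(tr$tip.label)  # validates, errors name the tip
  tr
}

#' @rdname read_newick
#' @param tree an \pkg{ape} `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read/write FASTA alignments with labelled sequences
#'
#' An alignment is a named character vector of equal-length uppercase
#' sequences over `A`, `C`, `G`, `T`, `-`; names parse as tip labels.
#' Files are wrapped at 80 columns.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    toupper(paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  }, "")
  names(seqs) <- sub("^>", "", trimws(lines[hdr]))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record names in ", path)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged FASTA: sequences have unequal lengths in ", path)
  bad <- grepl("[^ACGT-]", seqs)
  if (any(bad))
    stop("illegal character in sequence '", names(seqs)[bad][1], "'")
  parse_tip_labels(names(seqs))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of aligned sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (length(unique(nchar(seqs))) > 1L)
    stop("refusing to write ragged alignment")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}
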