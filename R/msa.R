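#' @include contacts.R
NULL

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' @param path alignment file
#' @param format "auto" (by extension/content), "fasta" or "clustal"
#' @return named character vector of gapped sequences
#' @export
readAlignmentFile <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    return(as.character(Biostrings::unmasked(aln)))
  }
  out <- tryCatch({
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    as.character(Biostrings::unmasked(aln))
  }, error = function(e) parseClustal(path))
  out
}

## lenient Clustal reader (plain 'name  sequence' blocks; conservation
## lines and block numbering ignored); strict files go through Biostrings
parseClustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a Clustal alignment: ", path)
  lines <- lines[-1]
  seqs <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation line
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2L) next
    chunk <- gsub("[0-9]", "", tok[2])
    seqs[[tok[1]]] <- paste0(if (is.null(seqs[[tok[1]]])) "" else
      seqs[[tok[1]]], chunk)
  }
  if (!length(seqs)) stop("no sequences found in Clustal file: ", path)
  w <- unique(nchar(unlist(seqs)))
  if (length(w) != 1L)
    stop("Clustal rows have unequal widths in ", path)
  unlist(seqs)
}

## profile -> one-letter sequence + channel values, ordered by residue
profileSequence <- function(profile, channel) {
  r <- profile@residues
  if (length(unique(r$chain)) > 1L)
    stop("profile spans multiple chains; subset to one chain or use ",
         "averageSubunits() first")
  r <- r[order(r$resseq, r$inscode), , drop = FALSE]
  list(seq = aa3to1(r$resname),
       values = r[[paste0(channel, "_fraction")]])
}

#' Project a contact profile onto an alignment row
#'
#' The k-th non-gap column of the row receives the k-th residue's contact
#' fraction for the chosen channel; gap columns receive NA. The row's
#' ungapped sequence must match the profile's residue sequence (an offset
#' into the profile may be supplied for trimmed constructs).
#'
#' @param row gapped sequence string (one alignment row)
#' @param profile a single-chain \linkS4class{ContactProfile} (see
#'   [averageSubunits()])
#' @param channel "headgroup" or "tail"
#' @param offset 0-based offset into the profile at which the row's
#'   sequence starts
#' @return numeric vector, one value per alignment column (NA at gaps)
#' @export
mapProfileToAlignment <- function(row, profile,
                                  channel = c("headgroup", "tail"),
                                  offset = 0L) {
  channel <- match.arg(channel)
  ps <- profileSequence(profile, channel)
  chars <- strsplit(row, "")[[1]]
  isgap <- chars %in% c("-", ".")
  rowseq <- chars[!isgap]
  need <- length(rowseq)
  avail <- length(ps$seq) - offset
  if (avail < need)
    stop("alignment row has ", need, " residues but the profile offers ",
         avail, " (after offset ", offset, "); supply the right offset")
  cmp <- ps$seq[offset + seq_len(need)]
  bad <- which(toupper(rowseq) != cmp)
  if (length(bad))
    stop("sequence mismatch at ungapped position ", bad[1], ": alignment '",
         rowseq[bad[1]], "' vs profile '", cmp[bad[1]], "'")
  if (avail > need && offset == 0L)
    stop("profile has ", avail - need, " residues beyond the row; supply ",
         "offset/trimming explicitly")
  vals <- rep(NA_real_, length(chars))
  vals[!isgap] <- ps$values[offset + seq_len(need)]
  vals
}

#' Aggregate per-sequence projections into a family view
#'
#' Per-column mean contact frequency over non-gap entries; all-gap columns
#' carry NA. Crystal-derived 0/1 profiles may be included; flag them via
#' names to keep the provenance visible.
#'
#' @param projections named list of numeric vectors from
#'   [mapProfileToAlignment()], all over the same alignment
#' @param alignment named character vector of the gapped rows (same order)
#' @param annotations optional per-column labels (e.g. helix H1-H6)
#' @return an \linkS4class{AlignmentProjection}
#' @export
aggregateFamily <- function(projections, alignment,
                            annotations = character(0)) {
  stopifnot(length(projections) >= 1L,
            length(projections) == length(alignment))
  w <- unique(vapply(projections, length, 1L))
  if (length(w) != 1L || any(nchar(alignment) != w))
    stop("projections and alignment rows must share one width ",
         "(inconsistent alignments?)")
  values <- do.call(rbind, projections)
  ids <- names(projections)
  if (is.null(ids)) ids <- names(alignment)
  if (is.null(ids)) ids <- paste0("seq", seq_along(projections))
  colMeansNA <- apply(values, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) NA_real_ else mean(v)
  })
  new("AlignmentProjection", ids = ids,
      alignment = unname(as.character(alignment)), values = values,
      columnMeans = colMeansNA, annotations = annotations)
}

#' Recover the ungapped profile vector from a projected row
#'
#' Drops gap columns of row \code{id}; the exact inverse of
#' [mapProfileToAlignment()].
#'
#' @param projection an \linkS4class{AlignmentProjection}
#' @param id sequence identifier (or row index)
#' @return numeric vector of per-residue values
#' @export
stripGaps <- function(projection, id) {
  i <- if (is.numeric(id)) id else match(id, projection@ids)
  if (is.na(i)) stop("no such sequence: ", id)
  chars <- strsplit(projection@alignment[i], "")[[1]]
  projection@values[i, !(chars %in% c("-", "."))]
}

#' Write an alignment projection as TSV
#'
#' One row per alignment column: position, optional annotation, family
#' mean, then one column per sequence (gaps empty).
#'
#' @param projection an \linkS4class{AlignmentProjection}
#' @param path output path
#' @export
writeProjection <- function(projection, path) {
  df <- data.frame(column = seq_len(ncol(projection@values)))
  if (length(projection@annotations))
    df$annotation <- projection@annotations
  df$family_mean <- projection@columnMeans
  vals <- t(projection@values)
  colnames(vals) <- projection@ids
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
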