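# Plain-text readers/writers: FASTA/FASTQ, the flowgram TSV dialect, and
# two-column clustering TSV. Gzip is handled transparently by extension.
# Malformed input fails loudly with a record/line diagnostic.

.read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

.open_text_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read and write FASTQ (Sanger, Phred+33)
#'
#' Strict 4-line-per-record FASTQ. Sequences are uppercased on read; `U` is
#' rejected (DNA only). Quality encoding is fixed to Phred+33 — no
#' autodetection, so qualities are never silently misread. A record whose
#' quality length differs from its sequence length is an error naming the
#' record. Round trips preserve ids, bases and qualities exactly.
#'
#' @param path file path (`.gz` transparently supported).
#' @return `read_fastq` returns a [read_set()] with qualities.
#' @export
read_fastq <- function(path) {
  lines <- .read_text_lines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(read_set(character(0), character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], " (line ", idx[bad[1L]],
         "): header does not start with '@'")
  plus <- lines[idx + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": separator line does not start with '+'")
  ids <- sub("^@", "", hdr)
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop("RNA (U) not supported; DNA input only")
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad))
    stop("FASTQ record '", ids[bad[1L]], "': invalid base character")
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop("FASTQ record '", ids[bad[1L]],
         "': quality length differs from sequence length")
  read_set(ids, seqs, quals)
}

#' @rdname read_fastq
#' @param reads a [read_set()] with qualities.
#' @return `write_fastq` returns `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "data.frame"))
  quals <- reads$quals
  quals[is.na(quals)] <- strrep("I", nchar(reads$bases[is.na(quals)]))
  con <- .open_text_out(path)
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste(paste0("@", reads$id), reads$bases, "+", quals,
                     sep = "\n"), con)
  invisible(path)
}

#' Read and write FASTA
#'
#' Backed by Biostrings. FASTA input carries no qualities, so downstream
#' denoising applies no quality gating.
#'
#' @param path file path.
#' @return `read_fasta` returns a [read_set()] without qualities.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  if (length(seqs) && any(grepl("[^ACGTN]", seqs)))
    stop("FASTA contains non-DNA characters")
  read_set(names(x), seqs)
}

#' @rdname read_fasta
#' @param reads a [read_set()].
#' @export
write_fasta <- function(reads, path) {
  stopifnot(inherits(reads, "data.frame"))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write the flowgram TSV dialect
#'
#' Line 1 is the header `#flow_order=TACG` (any permutation); each following
#' row is a read id then whitespace-separated decimal intensities. Negative
#' intensities are an error with the offending row number. Written
#' intensities carry 6 decimals, so round trips agree to that precision.
#'
#' @param path file path.
#' @return `read_flowgrams` returns a [flowgram_set()].
#' @export
read_flowgrams <- function(path) {
  lines <- .read_text_lines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "#flow_order="))
    stop("flowgram TSV must start with a '#flow_order=' header")
  order_str <- sub("^#flow_order=", "", lines[1L])
  flow_order <- strsplit(order_str, "", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ids <- character(length(body))
  intens <- vector("list", length(body))
  for (r in seq_along(body)) {
    cells <- strsplit(trimws(body[r]), "[\t ]+")[[1L]]
    if (length(cells) < 2L) stop("flowgram row ", r + 1L, ": no intensities")
    ids[r] <- cells[1L]
    f <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(f)) stop("flowgram row ", r + 1L, ": non-numeric intensity")
    if (any(f < 0)) stop("flowgram row ", r + 1L, ": negative intensity")
    intens[[r]] <- f
  }
  flowgram_set(ids, intens, flow_order)
}

#' @rdname read_flowgrams
#' @param flows a [flowgram_set()].
#' @export
write_flowgrams <- function(flows, path) {
  stopifnot(inherits(flows, "flowgram_set"))
  con <- .open_text_out(path)
  on.exit(close(con))
  writeLines(paste0("#flow_order=", paste(flows$flow_order, collapse = "")),
             con)
  for (r in seq_along(flows$id))
    writeLines(paste(c(flows$id[r], sprintf("%.6f", flows$intensities[[r]])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a two-column clustering TSV
#'
#' Rows are `read id <TAB> cluster label`; labels are opaque strings. Each id
#' may appear at most once.
#'
#' @param path file path.
#' @return a data frame of class `cluster_assignment` with columns `id` and
#'   `cluster`.
#' @export
read_clusters <- function(path) {
  lines <- .read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(cluster_assignment(character(0), character(0)))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != 2L)
  if (length(bad))
    stop("cluster TSV line ", bad[1L], ": expected 'id<TAB>label'")
  cluster_assignment(vapply(cells, `[`, "", 1L), vapply(cells, `[`, "", 2L))
}

#' Construct a cluster assignment
#'
#' @param id character vector of read ids (each at most once).
#' @param cluster parallel vector of cluster labels.
#' @return a data frame of class `cluster_assignment`.
#' @export
cluster_assignment <- function(id, cluster) {
  id <- as.character(id)
  cluster <- as.character(cluster)
  stopifnot(length(id) == length(cluster))
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate read id in clustering: '", dup[1L], "'")
  structure(data.frame(id = id, cluster = cluster, stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"))
}
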