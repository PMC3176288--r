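#' Read a reference FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences, validates the alphabet and tolerates an empty file (returning
#' an empty set), so that writer/reader pairs round-trip.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] (possibly empty), one element per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' as.character(readReferenceFasta(fa))  # "ACGT"
#' @export
readReferenceFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    ln <- readLines(path, warn = FALSE)
    if (!any(nzchar(trimws(ln))))
        return(Biostrings::DNAStringSet())
    if (!startsWith(trimws(ln[nzchar(trimws(ln))][1L]), ">"))
        stop("malformed FASTA (", path, "): first non-empty line is not a '>' header")
    bad <- which(!startsWith(ln, ">") & grepl("[^ACGTNacgtn[:space:]]", ln))
    if (length(bad))
        stop("illegal sequence characters in ", path, " at line ", bad[1L])
    seqs <- Biostrings::readDNAStringSet(path)
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(seqs, path) {
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Imports 3-6 column BED through [rtracklayer::import()]; intervals come
#' back 1-based inclusive as a [GenomicRanges::GRanges]. Strand defaults to
#' "+" when the file carries none; empty (zero-width) intervals are an
#' error.
#'
#' @param path path to a BED file.
#' @return A `GRanges` with the interval names (if any) in `name`.
#' @export
readBedIntervals <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    if (any(GenomicRanges::width(gr) < 1L))
        stop("BED file ", path, " contains empty intervals (start >= end)")
    st <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(st == "*", "+", st)
    gr
}

#' Write genomic intervals to BED
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a tab-separated table with schema validation
#'
#' The only table dialect used by the package is tab-separated text with a
#' header row; lines starting with `#` are metadata comments. Columns named
#' in `schema` must be present and are coerced to the stated type; a value
#' that fails numeric coercion is reported with its row number.
#'
#' @param path path to a TSV file.
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"numeric"` or `"integer"`). Extra columns are
#'   kept as read.
#' @return A `data.frame` (zero rows for a header-only file).
#' @export
readTsv <- function(path, schema = NULL) {
    if (!file.exists(path))
        stop("table not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    if (!is.null(schema)) {
        missing <- setdiff(names(schema), names(df))
        if (length(missing))
            stop("table ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
        for (col in names(schema)) {
            type <- schema[[col]]
            if (type %in% c("numeric", "integer")) {
                val <- suppressWarnings(as.numeric(df[[col]]))
                bad <- which(is.na(val) & !is.na(df[[col]]) & nzchar(df[[col]]))
                if (length(bad))
                    stop("non-numeric value in column '", col, "' of ", path,
                         " at data row ", bad[1L])
                df[[col]] <- if (type == "integer") as.integer(round(val)) else val
            }
        }
    }
    df
}

#' Write a tab-separated table with metadata header lines
#'
#' @param df a data.frame.
#' @param path output path.
#' @param meta named list/vector written as `#name=value` comment lines
#'   before the header (the run seed belongs here).
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path, meta = NULL) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(meta))
        writeLines(sprintf("#%s=%s", names(meta),
                           vapply(meta, as.character, character(1))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

# parse "#key=value" comment lines at the top of a TSV
readTsvMeta <- function(path) {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[startsWith(ln, "#")]
    ln <- ln[grepl("=", ln, fixed = TRUE)]
    if (!length(ln)) return(list())
    kv <- sub("^#", "", ln)
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(as.list(vals), keys)
}

#' Read a gene-level count table
#'
#' Expects a TSV with columns `gene_id` and `count` and a metadata line
#' `#library_size=<int>` giving the total number of uniquely mapped reads
#' for the library (which may exceed the column sum: reads can map outside
#' gene models).
#'
#' @param path path to the counts TSV.
#' @return A list with `counts` (named numeric vector, names = gene ids)
#'   and `librarySize`.
#' @export
readCountsTsv <- function(path) {
    meta <- readTsvMeta(path)
    if (is.null(meta$library_size))
        stop("counts file ", path, " lacks a '#library_size=<int>' header line")
    df <- readTsv(path, schema = c(gene_id = "character", count = "numeric"))
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene_id in ", path)
    lib <- as.numeric(meta$library_size)
    if (!is.finite(lib) || lib <= 0)
        stop("library_size in ", path, " must be a positive number")
    if (any(df$count > lib))
        stop("counts in ", path, " exceed the library size")
    list(counts = stats::setNames(df$count, df$gene_id), librarySize = lib)
}

#' Write a gene-level count table
#'
#' @param counts named numeric vector of per-gene counts.
#' @param librarySize total uniquely mapped reads.
#' @param path output path.
#' @param seed optional run seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writeCountsTsv <- function(counts, librarySize, path, seed = NULL) {
    meta <- list(library_size = librarySize)
    if (!is.null(seed)) meta$seed <- seed
    writeTsv(data.frame(gene_id = names(counts), count = as.numeric(counts)),
             path, meta = meta)
}

#' Read primer pairs from a TSV
#'
#' Expects columns `label`, `forward`, `reverse`.
#'
#' @param path path to the primer TSV.
#' @return A named list of [PrimerPair] objects.
#' @export
readPrimerPairs <- function(path) {
    df <- readTsv(path, schema = c(label = "character", forward = "character",
                                   reverse = "character"))
    prs <- lapply(seq_len(nrow(df)), function(i)
        PrimerPair(df$forward[i], df$reverse[i], df$label[i]))
    stats::setNames(prs, df$label)
}

#' Read a ranked predicted-target list
#'
#' Expects columns `rank` and `gene_id`; ranks must be unique.
#'
#' @param path path to the target-list TSV.
#' @return A data.frame with columns `rank` (integer) and `gene_id`,
#'   sorted by rank.
#' @export
readTargetList <- function(path) {
    df <- readTsv(path, schema = c(rank = "integer", gene_id = "character"))
    if (anyDuplicated(df$rank))
        stop("target list ", path, " has duplicate ranks")
    if (anyDuplicated(df$gene_id))
        stop("target list ", path, " has duplicate gene ids")
    df[order(df$rank), c("rank", "gene_id")]
}

#' Read per-interval fragment counts for Methyl-DIP enrichment
#'
#' The on-disk format is bedGraph-like: tab-separated `seq`, `start`, `end`,
#' `reads` with 0-based half-open coordinates, plus a `#library_size=<int>`
#' metadata line. Coordinates are converted to the package's 1-based
#' inclusive convention at ingest.
#'
#' @param path path to the fragment-count TSV.
#' @return A list with `intervals` (data.frame: seq, start, end, reads;
#'   1-based inclusive) and `librarySize`.
#' @export
readFragmentCounts <- function(path) {
    meta <- readTsvMeta(path)
    if (is.null(meta$library_size))
        stop("fragment-count file ", path, " lacks '#library_size=<int>'")
    df <- readTsv(path, schema = c(seq = "character", start = "integer",
                                   end = "integer", reads = "numeric"))
    if (any(df$start >= df$end))
        stop("fragment-count file ", path, " has empty intervals")
    df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
    list(intervals = df, librarySize = as.numeric(meta$library_size))
}

#' Write per-interval fragment counts
#'
#' @param intervals data.frame with `seq`, `start`, `end`, `reads`
#'   (1-based inclusive, as used in memory).
#' @param librarySize total captured fragments in the library.
#' @param path output path.
#' @param seed optional run seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writeFragmentCounts <- function(intervals, librarySize, path, seed = NULL) {
    out <- data.frame(seq = intervals$seq, start = intervals$start - 1L,
                      end = intervals$end, reads = intervals$reads)
    meta <- list(library_size = librarySize)
    if (!is.null(seed)) meta$seed <- seed
    writeTsv(out, path, meta = meta)
}
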