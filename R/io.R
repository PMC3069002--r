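IUPAC_CODES <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"), S = c("C", "G"),
    W = c("A", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a sequence record
#'
#' A sequence record pairs a unique taxon/strain label with an uppercase
#' nucleotide sequence over `A`, `C`, `G`, `T`, `N` (gap `-` is only legal
#' inside alignments; other IUPAC ambiguity codes only with
#' `allow_iupac = TRUE`).
#'
#' @param id Non-empty, unique label. Whitespace is not allowed (it separates
#'   the id from the description on a FASTA header line).
#' @param seq Nucleotide string; lowercase is normalised to uppercase.
#' @param description Free text.
#' @param gapped Allow `-` (alignment rows).
#' @param allow_iupac Accept ambiguity codes beyond `N`.
#' @return A list of class `seq_record` with fields `id`, `seq`,
#'   `description`.
#' @export
seq_record <- function(id, seq, description = "", gapped = FALSE,
                       allow_iupac = FALSE) {
    if (!is.character(id) || length(id) != 1L || !nzchar(id))
        stop("sequence id must be a non-empty string")
    seq <- toupper(seq)
    if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
    allowed <- c("A", "C", "G", "T", "N")
    if (allow_iupac) allowed <- names(IUPAC_CODES)
    if (gapped) allowed <- c(allowed, "-")
    bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), allowed)
    if (length(bad) > 0L)
        stop("record '", id, "' contains illegal characters: ",
             paste(bad, collapse = " "))
    structure(list(id = id, seq = seq, description = description),
              class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
    cat("<seq_record> ", x$id, " (", nchar(x$seq), " bp)\n", sep = "")
    invisible(x)
}

#' Read a multi-FASTA file
#'
#' @param path FASTA file.
#' @param gapped Keep `-` characters (used by [read_alignment()]).
#' @param allow_iupac Accept IUPAC ambiguity codes beyond `N`.
#' @return List of [seq_record()] objects, order preserved.
#' @export
read_fasta <- function(path, gapped = FALSE, allow_iupac = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("not readable as FASTA: ", path,
                                             " (", conditionMessage(e), ")"))
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0L)
        stop("duplicate sequence id(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    seqs <- as.character(set)
    recs <- mapply(function(i, s, d)
        seq_record(i, s, d, gapped = gapped, allow_iupac = allow_iupac),
        ids, seqs, desc, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    recs
}

#' Write sequence records as multi-FASTA (60-column wrap)
#'
#' @param records List of [seq_record()] (or a `multi_alignment`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
    if (inherits(records, "multi_alignment")) records <- records$records
    con <- file(path, "w")
    on.exit(close(con))
    for (r in records) {
        hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
        writeLines(paste0(">", hdr), con)
        n <- nchar(r$seq)
        starts <- seq(1L, n, by = 60L)
        writeLines(substring(r$seq, starts, pmin(starts + 59L, n)), con)
    }
    invisible(path)
}

#' Build a multiple alignment from gapped records
#'
#' @param records List of [seq_record()] whose sequences may contain `-`.
#' @return List of class `multi_alignment` with fields `records`, `ids`,
#'   `length`. All rows must have identical length; at least two rows.
#' @export
multi_alignment <- function(records) {
    if (length(records) < 2L) stop("an alignment needs at least 2 sequences")
    lens <- vapply(records, function(r) nchar(r$seq), integer(1))
    if (length(unique(lens)) != 1L) {
        ids <- vapply(records, function(r) r$id, character(1))
        mode_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
        off <- ids[lens != mode_len]
        stop("ragged alignment: record(s) ", paste(off, collapse = ", "),
             " deviate from the modal length ", mode_len)
    }
    structure(list(records = records,
                   ids = vapply(records, function(r) r$id, character(1)),
                   length = lens[[1]]),
              class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
    cat("<multi_alignment> ", length(x$records), " sequences x ",
        x$length, " columns\n", sep = "")
    invisible(x)
}

#' Read an aligned multi-FASTA file
#'
#' @inheritParams read_fasta
#' @return A `multi_alignment`.
#' @export
read_alignment <- function(path, allow_iupac = FALSE) {
    multi_alignment(read_fasta(path, gapped = TRUE, allow_iupac = allow_iupac))
}

# character matrix view (rows = taxa, columns = alignment columns)
aln_matrix <- function(aln) {
    m <- do.call(rbind, lapply(aln$records, function(r)
        strsplit(r$seq, "", fixed = TRUE)[[1]]))
    rownames(m) <- aln$ids
    m
}

matrix_to_alignment <- function(m) {
    multi_alignment(lapply(rownames(m), function(id)
        seq_record(id, paste(m[id, ], collapse = ""), gapped = TRUE,
                   allow_iupac = TRUE)))
}

#' Concatenate per-gene alignments across a common taxon set
#'
#' Joins each taxon's rows in the given gene order, recording partition
#' boundaries, as used for combined multi-gene fragments.
#'
#' @param alignments Named list of `multi_alignment` (names = gene labels).
#' @param taxa Taxon labels that must be present once in every alignment.
#' @return A `multi_alignment` with extra attribute `partitions`: data frame
#'   (gene, start, end) of 1-based column ranges.
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
    if (length(alignments) == 0L) stop("no alignments to concatenate")
    if (is.null(taxa)) taxa <- alignments[[1]]$ids
    genes <- names(alignments)
    if (is.null(genes)) genes <- paste0("gene", seq_along(alignments))
    for (g in seq_along(alignments)) {
        missing <- setdiff(taxa, alignments[[g]]$ids)
        if (length(missing) > 0L)
            stop("taxon '", missing[[1]], "' missing from alignment '",
                 genes[[g]], "'")
    }
    seqs <- vapply(taxa, function(tx) {
        paste(vapply(alignments, function(a)
            a$records[[match(tx, a$ids)]]$seq, character(1)), collapse = "")
    }, character(1))
    out <- multi_alignment(lapply(taxa, function(tx)
        seq_record(tx, seqs[[tx]], gapped = TRUE, allow_iupac = TRUE)))
    lens <- vapply(alignments, function(a) a$length, integer(1))
    ends <- cumsum(lens)
    attr(out, "partitions") <- data.frame(gene = genes,
                                          start = c(1L, head(ends, -1) + 1L),
                                          end = ends)
    out
}

#' Read a gene coordinate table
#'
#' Tab-separated with header `taxon  gene  start  end  strand`; coordinates
#' 1-based inclusive, strand `+` or `-`.
#'
#' @param path TSV file.
#' @return data.frame with those columns, validated.
#' @export
read_gene_coords <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("taxon", "gene", "start", "end", "strand")
    if (!all(need %in% names(df)))
        stop("coordinate table must have columns: ", paste(need, collapse = ", "))
    if (any(df$start < 1L) || any(df$start > df$end))
        stop("coordinates must satisfy 1 <= start <= end")
    if (!all(df$strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    df[need]
}

revcomp <- function(seq) {
    # IUPAC-aware reverse complement
    chartr("ACGTRYKMSWBDHVN-", "TGCAYRMKSWVHDBN-",
           paste(rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]]),
                 collapse = ""))
}
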