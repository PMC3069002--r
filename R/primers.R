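# minimal IUPAC code for a residue set, keyed by sorted concatenation
IUPAC_LOOKUP <- local({
    keys <- vapply(IUPAC_CODES, function(s) paste(sort(s), collapse = ""),
                   character(1))
    setNames(names(IUPAC_CODES), keys)
})

#' Degeneracy of an IUPAC primer sequence
#'
#' The number of distinct plain-nucleotide sequences the primer encodes:
#' the product over positions of the IUPAC alternative counts
#' (R = A/G counts 2, N counts 4, ...).
#'
#' @param iupac_seq IUPAC nucleotide string.
#' @return Integer >= 1.
#' @export
degeneracy <- function(iupac_seq) {
    chars <- strsplit(toupper(iupac_seq), "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, names(IUPAC_CODES))
    if (length(bad) > 0L)
        stop("illegal IUPAC symbol(s): ", paste(unique(bad), collapse = " "))
    prod(vapply(IUPAC_CODES[chars], length, integer(1)))
}

#' Degenerate IUPAC consensus of an alignment slice
#'
#' For each column in `start:end` the minimal IUPAC code covering the set of
#' observed residues. Gapped slices are rejected: primers cannot bind across
#' indels.
#'
#' @param aln A `multi_alignment`.
#' @param start,end 1-based alignment columns, inclusive.
#' @return IUPAC string of length `end - start + 1`.
#' @export
consensus_degenerate <- function(aln, start, end) {
    if (start < 1L || end > aln$length || start > end)
        stop("slice out of range")
    m <- aln_matrix(aln)[, start:end, drop = FALSE]
    gap <- which(m == "-", arr.ind = TRUE)
    if (nrow(gap) > 0L)
        stop("gap at row '", rownames(m)[gap[1, 1]], "', alignment column ",
             start + gap[1, 2] - 1L, ": cannot build a primer consensus")
    paste(vapply(seq_len(ncol(m)), function(j) {
        obs <- sort(unique(unlist(IUPAC_CODES[m[, j]], use.names = FALSE)))
        IUPAC_LOOKUP[[paste(obs, collapse = "")]]
    }, character(1)), collapse = "")
}

degenerate_primer <- function(name, iupac_seq, aln_start, aln_end,
                              orientation) {
    structure(list(name = name, iupac_seq = iupac_seq,
                   aln_start = aln_start, aln_end = aln_end,
                   orientation = orientation,
                   degeneracy = degeneracy(iupac_seq)),
              class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
    cat("<degenerate_primer> ", x$name, " ", x$iupac_seq, " (",
        x$orientation, ", cols ", x$aln_start, "-", x$aln_end,
        ", degeneracy ", x$degeneracy, ")\n", sep = "")
    invisible(x)
}

#' Construct a primer pair
#'
#' Reverse primers are stored as the reverse complement of the
#' template-strand consensus, i.e. in the 5'-3' orientation in which they
#' would be synthesised.
#'
#' @param fwd,rev `degenerate_primer` objects.
#' @param expected_product_range Numeric length-2, min/max product across
#'   the design taxa (both primers included).
#' @param anneal_temp Optional annealing temperature, degrees C (metadata).
#' @return List of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, expected_product_range = c(NA, NA),
                        anneal_temp = NA_real_) {
    structure(list(fwd = fwd, rev = rev,
                   expected_product_range = expected_product_range,
                   anneal_temp = anneal_temp),
              class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
    cat("<primer_pair> ", x$fwd$name, "/", x$rev$name, " product ",
        x$expected_product_range[1], "-", x$expected_product_range[2],
        " bp, degeneracy ", x$fwd$degeneracy, "x", x$rev$degeneracy,
        "\n", sep = "")
    invisible(x)
}

# candidate gap-free primer windows inside one conserved region
candidate_windows <- function(aln, m, region_start, region_end,
                              primer_len_range, max_degeneracy,
                              max_candidates) {
    out <- list()
    gapfree <- colSums(m == "-") == 0L
    for (len in primer_len_range[1]:primer_len_range[2]) {
        if (region_end - region_start + 1L < len) next
        for (s in region_start:(region_end - len + 1L)) {
            e <- s + len - 1L
            if (!all(gapfree[s:e])) next
            cons <- consensus_degenerate(aln, s, e)
            d <- degeneracy(cons)
            if (d > max_degeneracy) next
            out[[length(out) + 1L]] <- list(start = s, end = e,
                                            consensus = cons, degeneracy = d)
        }
    }
    if (length(out) == 0L) return(out)
    ord <- order(vapply(out, `[[`, numeric(1), "degeneracy"),
                 vapply(out, `[[`, numeric(1), "start"))
    out[ord][seq_len(min(length(out), max_candidates))]
}

#' Enumerate valid degenerate primer pairs over an alignment
#'
#' A valid pair has its forward primer inside one conserved region and its
#' reverse primer inside a later conserved region with at least one
#' hypervariable region strictly between them; the product (both primers
#' included, gaps discounted per taxon) lies within `product_range` for
#' every row of the alignment, and both primers respect `max_degeneracy`.
#'
#' @param aln A `multi_alignment` (one gene, all design taxa).
#' @param regions Output of [call_regions()] for `aln`.
#' @param primer_len_range Integer length-2; primer lengths to consider.
#' @param product_range Numeric length-2; allowed product size in bp
#'   (600-900 bp supports direct bidirectional sequencing with the PCR
#'   primers).
#' @param max_degeneracy Per-primer degeneracy ceiling.
#' @param max_candidates_per_region Keep only the least-degenerate windows
#'   per region before pairing (bounds the combinatorics).
#' @param name_prefix Prefix for generated primer names.
#' @return List of `primer_pair`, sorted by total degeneracy ascending then
#'   maximal product size descending. Empty list when no pair satisfies the
#'   constraints (a gene with fewer than two conserved regions can never
#'   yield one).
#' @export
enumerate_primer_pairs <- function(aln, regions,
                                   primer_len_range = c(17L, 22L),
                                   product_range = c(600, 900),
                                   max_degeneracy = 64,
                                   max_candidates_per_region = 40L,
                                   name_prefix = "p") {
    cons <- regions[regions$kind == "conserved", , drop = FALSE]
    if (nrow(cons) < 2L) return(list())
    hyper <- regions[regions$kind == "hypervariable", , drop = FALSE]
    m <- aln_matrix(aln)
    nongap <- apply(m != "-", 1L, cumsum)        # columns x taxa
    nongap <- rbind(0L, nongap)                  # row c+1 = count up to col c
    cands <- lapply(seq_len(nrow(cons)), function(i)
        candidate_windows(aln, m, cons$start[i], cons$end[i],
                          primer_len_range, max_degeneracy,
                          max_candidates_per_region))
    pairs <- list()
    for (i in seq_len(nrow(cons) - 1L)) {
        for (j in (i + 1L):nrow(cons)) {
            between <- hyper$start > cons$end[i] & hyper$end < cons$start[j]
            if (!any(between)) next
            for (wf in cands[[i]]) {
                for (wr in cands[[j]]) {
                    prod_len <- nongap[wr$end + 1L, ] - nongap[wf$start, ]
                    if (any(prod_len < product_range[1]) ||
                        any(prod_len > product_range[2])) next
                    fwd <- degenerate_primer(
                        paste0(name_prefix, wf$start, "F"), wf$consensus,
                        wf$start, wf$end, "forward")
                    rev <- degenerate_primer(
                        paste0(name_prefix, wr$end, "R"), revcomp(wr$consensus),
                        wr$start, wr$end, "reverse")
                    pairs[[length(pairs) + 1L]] <- primer_pair(
                        fwd, rev, range(prod_len))
                }
            }
        }
    }
    if (length(pairs) == 0L) return(pairs)
    totdeg <- vapply(pairs, function(p)
        p$fwd$degeneracy + p$rev$degeneracy, numeric(1))
    maxprod <- vapply(pairs, function(p) p$expected_product_range[2], numeric(1))
    pairs[order(totdeg, -maxprod)]
}

# IUPAC-aware primer site scan on the plus strand of a template.
# Returns starts (1-based) and mismatch counts for windows with
# <= max_mismatch mismatches and an exact 3'-terminal `exact_3p` stretch.
# `three_prime` = "right" when the primer's 3' end is the window's right
# end (left/forward primer), "left" for a right/reverse primer site.
scan_primer_sites <- function(tpl_chars, primer, max_mismatch = 0L,
                              exact_3p = 3L, three_prime = "right") {
    L <- nchar(primer)
    n <- length(tpl_chars)
    if (n < L) return(data.frame(start = integer(0), mismatches = integer(0)))
    pc <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
    nwin <- n - L + 1L
    mm <- integer(nwin)
    ok3 <- rep(TRUE, nwin)
    if (three_prime == "right") p3 <- (L - exact_3p + 1L):L else p3 <- 1:exact_3p
    for (p in seq_len(L)) {
        okp <- tpl_chars[p:(p + nwin - 1L)] %in% IUPAC_CODES[[pc[p]]]
        mm <- mm + !okp
        if (p %in% p3) ok3 <- ok3 & okp
    }
    hit <- which(mm <= max_mismatch & ok3)
    data.frame(start = hit, mismatches = mm[hit])
}

#' In-silico PCR of a degenerate primer pair on a template
#'
#' Finds every site where the forward primer matches (IUPAC set-membership:
#' a template base matches if it belongs to the primer code's set) with at
#' most `max_mismatch` mismatches, and the reverse primer's reverse
#' complement matches downstream within `max_product`. Both orientations of
#' the template are searched. The 3'-terminal `exact_3p` bases of each
#' primer must match exactly regardless of `max_mismatch` (polymerase
#' extension requires an annealed 3' end). An empty result models a
#' PCR-negative template.
#'
#' @param template A [seq_record()] (ungapped) or plain string.
#' @param pair A `primer_pair`.
#' @param max_mismatch Allowed mismatches per primer outside the 3' end.
#' @param max_product Largest product reported, bp.
#' @param exact_3p Number of 3'-terminal bases requiring exact match.
#' @return data.frame (class `amplicon_table`) with columns `taxon`,
#'   `start`, `end` (1-based, product including both primers), `length`,
#'   `strand`, `fwd_mismatches`, `rev_mismatches`. Attribute `nonspecific`
#'   is TRUE when more than one product was found.
#' @export
insilico_pcr <- function(template, pair, max_mismatch = 0L,
                         max_product = 5000L, exact_3p = 3L) {
    if (is.character(template)) template <- seq_record("template", template)
    if (grepl("-", template$seq, fixed = TRUE))
        stop("template must be ungapped")
    tpl <- strsplit(template$seq, "", fixed = TRUE)[[1]]
    fwd <- pair$fwd$iupac_seq
    rev <- pair$rev$iupac_seq
    Lf <- nchar(fwd); Lr <- nchar(rev)
    res <- list()
    add <- function(s, e, strand, fmm, rmm) {
        res[[length(res) + 1L]] <<- data.frame(
            taxon = template$id, start = s, end = e, length = e - s + 1L,
            strand = strand, fwd_mismatches = fmm, rev_mismatches = rmm)
    }
    # plus-strand product: fwd on the left, revcomp(rev) on the right
    fs <- scan_primer_sites(tpl, fwd, max_mismatch, exact_3p, "right")
    rs <- scan_primer_sites(tpl, revcomp(rev), max_mismatch, exact_3p, "left")
    for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
        s <- fs$start[i]; e <- rs$start[j] + Lr - 1L
        len <- e - s + 1L
        if (len >= Lf + Lr && len <= max_product)
            add(s, e, "+", fs$mismatches[i], rs$mismatches[j])
    }
    # minus-strand product: rev on the left, revcomp(fwd) on the right
    ls <- scan_primer_sites(tpl, rev, max_mismatch, exact_3p, "right")
    gs <- scan_primer_sites(tpl, revcomp(fwd), max_mismatch, exact_3p, "left")
    for (i in seq_len(nrow(ls))) for (j in seq_len(nrow(gs))) {
        s <- ls$start[i]; e <- gs$start[j] + Lf - 1L
        len <- e - s + 1L
        if (len >= Lf + Lr && len <= max_product)
            add(s, e, "-", gs$mismatches[j], ls$mismatches[i])
    }
    out <- if (length(res) == 0L)
        data.frame(taxon = character(0), start = integer(0), end = integer(0),
                   length = integer(0), strand = character(0),
                   fwd_mismatches = integer(0), rev_mismatches = integer(0))
    else do.call(rbind, res)
    attr(out, "nonspecific") <- nrow(out) > 1L
    class(out) <- c("amplicon_table", "data.frame")
    out
}

#' The broad-range Actinobacteridae primer set
#'
#' The three published degenerate primer pairs targeting `rpoB`, `secY` and
#' `ychF` that this selection pipeline was developed around, with their
#' expected amplicon sizes on the M. tuberculosis reference numbering and
#' annealing temperatures. Useful as a realistic input for in-silico PCR
#' when a suitable actinobacterial genome is available.
#'
#' @return data.frame with columns `gene`, `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq`, `expected_bp`, `anneal_c`.
#' @export
actino_primer_set <- function() {
    data.frame(
        gene = c("rpoB", "secY", "ychF"),
        fwd_name = c("ActRpoB2473F", "ActSECY238F", "ActYCHF208F"),
        fwd_seq = c("GGHAAGGTSACSCCNAAGGG", "GGBRTBATGCCSTACATYAC",
                    "TTYGTBGAYATCGCVGG"),
        rev_name = c("ActRpoB3303R", "ActSECY1109R", "ActYCHF983R"),
        rev_seq = c("GAANCGCTGDCCRCCGAACTG", "AANCCRCCRWACTKCTTCAT",
                    "ACGAYYTCVGCYTTGATGAA"),
        expected_bp = c(754L, 787L, 703L),
        anneal_c = c(60, 52, 52),
        stringsAsFactors = FALSE)
}

#' Write primer pairs as TSV
#'
#' @param pairs List of `primer_pair`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(pairs, path) {
    df <- do.call(rbind, lapply(pairs, function(p) data.frame(
        fwd_name = p$fwd$name, fwd_seq = p$fwd$iupac_seq,
        fwd_degeneracy = p$fwd$degeneracy,
        rev_name = p$rev$name, rev_seq = p$rev$iupac_seq,
        rev_degeneracy = p$rev$degeneracy,
        product_min = p$expected_product_range[1],
        product_max = p$expected_product_range[2])))
    if (is.null(df)) df <- data.frame()
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
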