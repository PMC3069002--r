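#' Build a gene catalogue
#'
#' A catalogue entry holds one candidate gene's ungapped sequence per taxon
#' (absences allowed), a functional category, and flags from
#' `{ribosomal, aaRS, hgt_suspect}` used by the exclusion filter. HGT
#' evidence is supplied as a flag (literature-based), never computed.
#'
#' @param entries List of lists with fields `gene`, `category`, `seqs`
#'   (named list/character, taxon -> sequence), `flags` (character vector).
#' @return List of class `gene_catalogue`, names = gene names.
#' @export
gene_catalogue <- function(entries) {
    genes <- vapply(entries, function(e) e$gene, character(1))
    if (anyDuplicated(genes)) stop("duplicate gene names in catalogue")
    entries <- lapply(entries, function(e) {
        e$flags <- as.character(e$flags %||% character(0))
        e$category <- e$category %||% ""
        e$seqs <- lapply(e$seqs, toupper)
        if (any(grepl("-", unlist(e$seqs), fixed = TRUE)))
            stop("catalogue sequences must be ungapped (gene '", e$gene, "')")
        e
    })
    structure(setNames(entries, genes), class = "gene_catalogue")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length filter over a gene catalogue
#'
#' A gene passes iff its median ungapped sequence length across taxa is at
#' least `min_len`. Genes under 900 bp carry too little phylogenetic signal
#' for a sequenced fragment; the median resists annotation outliers.
#'
#' @param catalogue A `gene_catalogue`.
#' @param min_len Minimum length in bp (strictly-less fails).
#' @return data.frame (gene, median_len, pass).
#' @export
filter_by_length <- function(catalogue, min_len = 900) {
    rows <- lapply(catalogue, function(e) {
        if (length(e$seqs) == 0L)
            stop("gene '", e$gene, "' has no sequences")
        ml <- median(vapply(e$seqs, nchar, integer(1)))
        data.frame(gene = e$gene, median_len = ml, pass = ml >= min_len)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Ubiquity filter
#'
#' A gene passes iff a sequence exists for every requested taxon. Markers
#' missing from part of the clade cannot anchor a universal MLSA scheme.
#'
#' @param catalogue A `gene_catalogue`.
#' @param taxa Character vector of required taxon labels.
#' @return data.frame (gene, n_present, n_required, pass, note).
#' @export
ubiquity_check <- function(catalogue, taxa) {
    if (length(taxa) == 0L) stop("taxa must be non-empty")
    rows <- lapply(catalogue, function(e) {
        present <- intersect(taxa, names(e$seqs))
        note <- if (length(present) == 0L) "absent in all" else ""
        data.frame(gene = e$gene, n_present = length(present),
                   n_required = length(taxa),
                   pass = length(present) == length(taxa), note = note)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Count gene copies in a genome by seed-and-extend local search
#'
#' Counts non-overlapping genomic loci whose alignment to the gene reaches
#' at least `min_identity` over at least `min_coverage` of the gene length.
#' Seeding uses exact k-mers (`k = 12`) on both strands; each seed cluster
#' is verified by global alignment of the spanned genomic segment against
#' the gene. A count above 1 reveals a duplicate or close paralogue that
#' would confound single-locus sequencing.
#'
#' @param genome A [seq_record()] or plain string.
#' @param gene_seq Ungapped gene sequence (>= 100 bp).
#' @param min_identity,min_coverage Acceptance thresholds in \[0, 1\].
#' @param k Seed k-mer length.
#' @return Integer copy count (0 when no homologous locus exists).
#' @export
copy_number <- function(genome, gene_seq, min_identity = 0.70,
                        min_coverage = 0.70, k = 12L) {
    if (is.character(genome)) genome <- seq_record("genome", genome)
    gene_seq <- toupper(gene_seq)
    glen <- nchar(gene_seq)
    if (glen < 100L) stop("gene_seq must be at least 100 bp")
    hits <- list()
    for (strand in c("+", "-")) {
        g <- if (strand == "+") genome$seq else revcomp(genome$seq)
        loci <- seed_loci(g, gene_seq, k)
        for (iv in loci) {
            seg <- substr(g, iv[1], iv[2])
            al <- .nw_align(seg, gene_seq, 1, -1, -2, -2)
            ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
            cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
            covered <- sum(ca != "-" & cb != "-")   # gene bases the locus aligns
            idy <- if (covered > 0L) al$matched / covered else 0
            cov <- covered / glen
            if (idy >= min_identity && cov >= min_coverage) {
                # map back to plus-strand coordinates for overlap merging
                s <- iv[1]; e <- iv[2]
                if (strand == "-") {
                    n <- nchar(genome$seq)
                    s2 <- n - e + 1L; e2 <- n - iv[1] + 1L
                    s <- s2; e <- e2
                }
                hits[[length(hits) + 1L]] <- c(s, e)
            }
        }
    }
    if (length(hits) == 0L) return(0L)
    iv <- do.call(rbind, hits)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    count <- 1L
    cur_end <- iv[1, 2]
    for (i in seq_len(nrow(iv))[-1]) {
        if (iv[i, 1] > cur_end) {
            count <- count + 1L
            cur_end <- iv[i, 2]
        } else cur_end <- max(cur_end, iv[i, 2])
    }
    count
}

# cluster exact k-mer seed hits by diagonal into candidate genomic intervals
seed_loci <- function(genome_seq, gene_seq, k) {
    n <- nchar(genome_seq)
    glen <- nchar(gene_seq)
    if (n < k || glen < k) return(list())
    gkmers <- substring(genome_seq, 1:(n - k + 1L), k:n)
    qkmers <- substring(gene_seq, 1:(glen - k + 1L), k:glen)
    idx <- split(seq_along(gkmers), gkmers)
    hit_q <- which(qkmers %in% names(idx))
    if (length(hit_q) == 0L) return(list())
    gpos <- unlist(idx[qkmers[hit_q]], use.names = FALSE)
    qpos <- rep(hit_q, vapply(idx[qkmers[hit_q]], length, integer(1)))
    diag <- gpos - qpos
    ord <- order(diag, gpos)
    diag <- diag[ord]; gpos <- gpos[ord]; qpos <- qpos[ord]
    # group hits whose diagonals lie within a tolerance band
    grp <- cumsum(c(TRUE, diff(diag) > 30L))
    loci <- lapply(split(seq_along(grp), grp), function(ii) {
        span_q <- max(qpos[ii]) - min(qpos[ii]) + k
        if (span_q < 0.3 * glen) return(NULL)
        d <- stats::median(diag[ii])
        s <- max(1L, as.integer(d + 1L - 0.1 * glen))
        e <- min(n, as.integer(d + glen + 0.1 * glen))
        c(s, e)
    })
    loci <- loci[!vapply(loci, is.null, logical(1))]
    # merge near-identical candidate intervals
    if (length(loci) > 1L) {
        iv <- do.call(rbind, loci)
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        merged <- list(iv[1, ])
        for (i in seq_len(nrow(iv))[-1]) {
            last <- merged[[length(merged)]]
            if (iv[i, 1] <= last[2] - k) {
                merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
            } else merged[[length(merged) + 1L]] <- iv[i, ]
        }
        loci <- merged
    }
    loci
}

#' Flag closely linked gene pairs
#'
#' Genes whose genomic gap on the same replicon is below `min_separation`
#' are linked (e.g. operonic neighbours such as rpoB-rpoC); linked genes
#' sample correlated evolutionary histories and should not both enter an
#' MLSA scheme. A pair is flagged globally when linked in a majority of the
#' taxa carrying both genes. Overlapping annotations are flagged, not
#' errors.
#'
#' @param coords data.frame as from [read_gene_coords()].
#' @param min_separation Gap threshold in bp.
#' @return data.frame (gene_a, gene_b, n_taxa, n_linked, linked).
#' @export
linkage_check <- function(coords, min_separation = 10000) {
    genes <- sort(unique(coords$gene))
    if (length(genes) < 2L) stop("need coordinates for at least 2 genes")
    pairs <- combn(genes, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(p) {
        ga <- pairs[1, p]; gb <- pairs[2, p]
        taxa <- intersect(coords$taxon[coords$gene == ga],
                          coords$taxon[coords$gene == gb])
        linked_in <- vapply(taxa, function(tx) {
            a <- coords[coords$gene == ga & coords$taxon == tx, ][1, ]
            b <- coords[coords$gene == gb & coords$taxon == tx, ][1, ]
            gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
            gap < min_separation            # overlap gives negative gap
        }, logical(1))
        data.frame(gene_a = ga, gene_b = gb, n_taxa = length(taxa),
                   n_linked = sum(linked_in),
                   linked = length(taxa) > 0L &&
                       sum(linked_in) > length(taxa) / 2)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Screen a gene catalogue through the full candidate filter funnel
#'
#' Applies, in order: flag exclusions (ribosomal proteins and
#' aminoacyl-tRNA synthetase/HGT-suspect genes), the 900 bp length filter,
#' ubiquity across taxa, and the single-copy check; genomic linkage between
#' surviving genes is reported alongside. Every criterion is evaluated and
#' recorded for every gene (no short-circuiting), so the report shows the
#' complete elimination funnel.
#'
#' @param catalogue A `gene_catalogue`.
#' @param taxa Required taxon labels.
#' @param coords Optional coordinate table for the linkage report.
#' @param genomes Optional named list of [seq_record()] (taxon -> genome)
#'   enabling the copy-number criterion; a gene fails if any genome carries
#'   more than one copy.
#' @param exclusions Flags whose carriers are excluded
#'   (default `c("ribosomal", "aaRS", "hgt_suspect")`).
#' @param min_len,min_separation Filter parameters.
#' @return List of class `screen_report`: `verdicts` (data.frame with one
#'   row per gene: pass/fail per criterion, overall `pass`,
#'   `failed_criteria`), `survivors` (character), `linked_pairs`
#'   (data.frame or NULL), `counts` (named vector of survivors after each
#'   stage).
#' @export
screen <- function(catalogue, taxa, coords = NULL, genomes = NULL,
                   exclusions = c("ribosomal", "aaRS", "hgt_suspect"),
                   min_len = 900, min_separation = 10000) {
    genes <- names(catalogue)
    excl_pass <- vapply(catalogue, function(e)
        !any(e$flags %in% exclusions), logical(1))
    len <- filter_by_length(catalogue, min_len)
    ubi <- ubiquity_check(catalogue, taxa)
    copy_ok <- rep(TRUE, length(genes))
    copies_max <- rep(NA_integer_, length(genes))
    if (!is.null(genomes)) {
        for (i in seq_along(genes)) {
            e <- catalogue[[i]]
            cn <- vapply(intersect(names(genomes), names(e$seqs)),
                         function(tx) copy_number(genomes[[tx]],
                                                  e$seqs[[tx]]), integer(1))
            copies_max[i] <- if (length(cn)) max(cn) else NA_integer_
            copy_ok[i] <- all(cn <= 1L)
        }
    }
    verdicts <- data.frame(
        gene = genes,
        excluded_flag = !excl_pass,
        length_pass = len$pass[match(genes, len$gene)],
        median_len = len$median_len[match(genes, len$gene)],
        ubiquity_pass = ubi$pass[match(genes, ubi$gene)],
        copy_pass = copy_ok,
        max_copies = copies_max,
        stringsAsFactors = FALSE)
    verdicts$pass <- !verdicts$excluded_flag & verdicts$length_pass &
        verdicts$ubiquity_pass & verdicts$copy_pass
    verdicts$failed_criteria <- vapply(seq_along(genes), function(i) {
        f <- c(if (verdicts$excluded_flag[i]) "excluded",
               if (!verdicts$length_pass[i]) "length",
               if (!verdicts$ubiquity_pass[i]) "ubiquity",
               if (!verdicts$copy_pass[i]) "copy_number")
        paste(f, collapse = ",")
    }, character(1))
    survivors <- genes[verdicts$pass]
    linked <- NULL
    if (!is.null(coords) && length(unique(coords$gene)) >= 2L)
        linked <- linkage_check(coords, min_separation)
    counts <- c(input = length(genes),
                after_exclusion = sum(excl_pass),
                after_length = sum(excl_pass & verdicts$length_pass),
                after_ubiquity = sum(excl_pass & verdicts$length_pass &
                                     verdicts$ubiquity_pass),
                after_copy_number = length(survivors))
    structure(list(verdicts = verdicts, survivors = survivors,
                   linked_pairs = linked, counts = counts),
              class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
    cat("<screen_report> ", x$counts[["input"]], " genes -> ",
        length(x$survivors), " survivors\n", sep = "")
    print(x$counts)
    invisible(x)
}
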