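#' Percent identity between two sequences
#'
#' For aligned input (equal lengths, gaps allowed) identity is the number
#' of identical non-gap columns divided by the number of columns with at
#' least one non-gap residue; columns where both sequences gap are skipped,
#' columns with a single gap count as mismatches. Unaligned input is
#' globally aligned first (match +1, mismatch -1, gap -2).
#'
#' @param seq_a,seq_b Sequences (strings or [seq_record()]).
#' @param aligned Are the inputs already aligned?
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(seq_a, seq_b, aligned = TRUE) {
    a <- as_seqstring(seq_a); b <- as_seqstring(seq_b)
    if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
    if (!aligned) {
        if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
            stop("unaligned input must be ungapped")
        al <- .nw_align(a, b, 1, -1, -2, -2)
        a <- al$aligned_a; b <- al$aligned_b
    } else if (nchar(a) != nchar(b)) {
        stop("aligned sequences must have equal length")
    }
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    keep <- !(ca == "-" & cb == "-")
    if (!any(keep)) stop("no comparable columns")
    100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep)
}

#' Pair gene-fragment similarity (SS) with genome conserved relatedness (GCR)
#'
#' Builds one row per unordered taxon pair, combining the fragment percent
#' identity computed from aligned per-taxon sequences with a precomputed
#' genome conserved-region similarity.
#'
#' @param fragments Named list/character, taxon -> aligned fragment
#'   sequence (equal lengths).
#' @param genome_sims Named numeric: `"taxonA|taxonB"` (labels sorted) ->
#'   GCR percent, or a data.frame with columns `taxon_a`, `taxon_b`, `gcr`.
#' @param dedup_identical Collapse taxa whose fragments are 100% identical
#'   to an earlier taxon (one sequence per taxon retained, avoiding primer
#'   bias toward over-represented strains). Off by default.
#' @return data.frame (taxon_a, taxon_b, ss, gcr).
#' @export
build_pairs <- function(fragments, genome_sims, dedup_identical = FALSE) {
    taxa <- names(fragments)
    if (is.data.frame(genome_sims)) {
        key <- pair_key(genome_sims$taxon_a, genome_sims$taxon_b)
        genome_sims <- setNames(genome_sims$gcr, key)
    }
    if (dedup_identical && length(taxa) > 1L) {
        keep <- taxa[1]
        for (tx in taxa[-1]) {
            dup <- any(vapply(keep, function(k)
                pairwise_identity(fragments[[k]], fragments[[tx]]) == 100,
                logical(1)))
            if (!dup) keep <- c(keep, tx)
        }
        taxa <- keep
    }
    if (length(taxa) < 2L)
        return(data.frame(taxon_a = character(0), taxon_b = character(0),
                          ss = numeric(0), gcr = numeric(0)))
    prs <- combn(taxa, 2L)
    keys <- pair_key(prs[1, ], prs[2, ])
    missing <- keys[!(keys %in% names(genome_sims))]
    if (length(missing) > 0L)
        stop("missing genome similarity for pair(s): ",
             paste(missing, collapse = ", "))
    data.frame(
        taxon_a = prs[1, ], taxon_b = prs[2, ],
        ss = vapply(seq_len(ncol(prs)), function(i)
            pairwise_identity(fragments[[prs[1, i]]], fragments[[prs[2, i]]]),
            numeric(1)),
        gcr = unname(genome_sims[keys]),
        stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
    vapply(seq_along(a), function(i)
        paste(sort(c(a[i], b[i])), collapse = "|"), character(1))
}

#' Least-squares quadratic regression of GCR on fragment similarity
#'
#' Fits `gcr = a * ss^2 + b * ss + c` by ordinary least squares on the
#' percent scale and reports the coefficient of determination. The fitted
#' curve is the gene's genome-relatedness prediction model; genes are
#' ranked by its R-squared.
#'
#' @param pairs data.frame with `ss` and `gcr` columns (percent scale), as
#'   from [build_pairs()].
#' @param gene_label Label stored with the model.
#' @return List of class `quadratic_gcr_model`: `gene`, `a`, `b`, `c`,
#'   `r2`, `n_pairs`, `ss_range`, `fit` (the underlying `lm`).
#' @export
fit_quadratic <- function(pairs, gene_label = "gene") {
    if (nrow(pairs) < 3L) stop("need at least 3 pairs")
    if (length(unique(pairs$ss)) < 3L)
        stop("degenerate design: need at least 3 distinct ss values")
    fit <- lm(gcr ~ I(ss^2) + ss, data = pairs)
    cf <- coef(fit)
    ssres <- sum(residuals(fit)^2)
    sstot <- sum((pairs$gcr - mean(pairs$gcr))^2)
    structure(list(gene = gene_label,
                   a = unname(cf[["I(ss^2)"]]), b = unname(cf[["ss"]]),
                   c = unname(cf[["(Intercept)"]]),
                   r2 = 1 - ssres / sstot,
                   n_pairs = nrow(pairs),
                   ss_range = range(pairs$ss),
                   fit = fit),
              class = "quadratic_gcr_model")
}

#' @export
print.quadratic_gcr_model <- function(x, ...) {
    cat(sprintf("<quadratic_gcr_model> %s: GCR = %.4gSS^2 %+.4gSS %+.4g (R2 = %.3f, n = %d)\n",
                x$gene, x$a, x$b, x$c, x$r2, x$n_pairs))
    invisible(x)
}

#' Build a quadratic GCR model from given coefficients
#'
#' Wraps published or externally fitted coefficients (percent scale) so
#' they can be evaluated with [predict_gcr()].
#'
#' @param a,b,c Coefficients of `a*ss^2 + b*ss + c`.
#' @param gene_label Label.
#' @param r2,n_pairs,ss_range Optional metadata.
#' @return A `quadratic_gcr_model`.
#' @export
quadratic_gcr_model <- function(a, b, c, gene_label = "model",
                                r2 = NA_real_, n_pairs = NA_integer_,
                                ss_range = c(NA_real_, NA_real_)) {
    structure(list(gene = gene_label, a = a, b = b, c = c, r2 = r2,
                   n_pairs = n_pairs, ss_range = ss_range, fit = NULL),
              class = "quadratic_gcr_model")
}

#' Predict genome conserved relatedness from fragment similarity
#'
#' Evaluates `a*ss^2 + b*ss + c` on the percent scale, clamps the result to
#' \[0, 100\], and flags predictions outside the model's observed SS range
#' (extrapolation) and clamped values.
#'
#' @param model A `quadratic_gcr_model`.
#' @param ss Fragment similarity, percent (vectorised).
#' @return Numeric vector with attributes `clamped` and `extrapolated`
#'   (logical vectors).
#' @export
predict_gcr <- function(model, ss) {
    raw <- model$a * ss^2 + model$b * ss + model$c
    clamped <- raw < 0 | raw > 100
    extrap <- if (all(is.na(model$ss_range))) rep(FALSE, length(ss))
              else ss < model$ss_range[1] | ss > model$ss_range[2]
    out <- pmin(100, pmax(0, raw))
    attr(out, "clamped") <- clamped
    attr(out, "extrapolated") <- extrap
    out
}

#' Rank gene models by R-squared and select the predictive set
#'
#' @param models List of `quadratic_gcr_model`.
#' @param r2_threshold Genes with `r2` strictly above it are selected.
#' @return List: `ranking` (data.frame gene/a/b/c/r2/n_pairs sorted by r2
#'   descending), `selected` (character vector of gene labels).
#' @export
rank_genes <- function(models, r2_threshold = 0.85) {
    if (length(models) == 0L) stop("need at least one model")
    df <- do.call(rbind, lapply(models, function(m) data.frame(
        gene = m$gene, a = m$a, b = m$b, c = m$c, r2 = m$r2,
        n_pairs = m$n_pairs, stringsAsFactors = FALSE)))
    df <- df[order(-df$r2), , drop = FALSE]
    rownames(df) <- NULL
    list(ranking = df, selected = df$gene[df$r2 > r2_threshold])
}

#' Intraspecies fragment-similarity summary
#'
#' For each species with at least two strains, the minimum and maximum
#' pairwise percent identity over all within-species strain pairs; species
#' with a single strain are skipped with a notice. Observed intraspecies
#' minima delineate candidate species-level similarity cutoffs.
#'
#' @param labeled_fragments Named list: species -> named list/character of
#'   aligned strain sequences.
#' @param aligned Are strain sequences aligned within species?
#' @return data.frame (species, n_strains, min_similarity, max_similarity).
#' @export
intraspecies_summary <- function(labeled_fragments, aligned = TRUE) {
    rows <- list()
    for (sp in names(labeled_fragments)) {
        seqs <- labeled_fragments[[sp]]
        if (length(seqs) < 2L) {
            message("skipping species '", sp, "': fewer than 2 strains")
            next
        }
        prs <- combn(length(seqs), 2L)
        sims <- vapply(seq_len(ncol(prs)), function(i)
            pairwise_identity(seqs[[prs[1, i]]], seqs[[prs[2, i]]],
                              aligned = aligned), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
            species = sp, n_strains = length(seqs),
            min_similarity = min(sims), max_similarity = max(sims),
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(species = character(0), n_strains = integer(0),
                          min_similarity = numeric(0),
                          max_similarity = numeric(0)))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
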