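#' Default pipeline parameters
#'
#' Every stage parameter in one place: variability window 50 with
#' conserved threshold 15 percent, primer product range 600-900 bp with
#' per-primer degeneracy up to 64, genome anchoring with minMatch 12,
#' maxGap 250, diagFactor 0.15, minCluster 40 and breaklen 500, the 900 bp
#' gene-length floor, 10 kb linkage separation, R-squared selection
#' threshold 0.85, and 1000 bootstrap replicates summarised at 65 percent
#' support.
#'
#' @param ... Overrides for individual parameters.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
    p <- list(window = 50L, step = 50L, conserved_threshold = 15,
              min_conserved_windows = 1L,
              primer_len_range = c(17L, 22L), product_range = c(600, 900),
              max_degeneracy = 64, min_len = 900, min_separation = 10000,
              min_match = 12L, max_gap = 250, diag_factor = 0.15,
              min_cluster = 40, breaklen = 500,
              r2_threshold = 0.85, n_boot = 1000L, support_threshold = 65)
    over <- list(...)
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0L)
        stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
    p
}

#' Genome conserved-region similarity for every genome pair
#'
#' @param genomes Named list of [seq_record()].
#' @param params [pipeline_params()].
#' @return data.frame (taxon_a, taxon_b, gcr, covered_ref, covered_query).
#' @export
all_pairs_gcr <- function(genomes, params = pipeline_params()) {
    taxa <- names(genomes)
    prs <- combn(taxa, 2L)
    rows <- lapply(seq_len(ncol(prs)), function(i) {
        cs <- conserved_similarity(
            genomes[[prs[1, i]]], genomes[[prs[2, i]]],
            min_match = params$min_match, max_gap = params$max_gap,
            diag_factor = params$diag_factor,
            min_cluster = params$min_cluster, breaklen = params$breaklen)
        data.frame(taxon_a = prs[1, i], taxon_b = prs[2, i],
                   gcr = cs$gcr_similarity,
                   covered_ref = cs$covered_fraction_ref,
                   covered_query = cs$covered_fraction_query)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' End-to-end MLSA core-gene selection
#'
#' Chains the full funnel on a catalogue of candidate genes and their
#' source genomes: screening (exclusion flags, length, ubiquity, copy
#' number; linkage reported) -> windowed variability profiling and
#' conserved/hypervariable region calls -> degenerate primer-pair
#' enumeration -> in-silico PCR (genes amplifying non-specifically or not
#' at all in any taxon are dropped) -> fragment extraction between the
#' primers (primer binding sites excluded) -> whole-genome conserved-region
#' similarity for every genome pair -> per-gene quadratic GCR regression
#' and R-squared ranking -> concatenation of the selected fragments and a
#' bootstrapped neighbor-joining tree.
#'
#' @param catalogue A `gene_catalogue`.
#' @param genomes Named list of [seq_record()], taxon -> genome.
#' @param coords Optional gene coordinate table (linkage report).
#' @param params [pipeline_params()].
#' @param seed Seed for the bootstrap stage (mandatory).
#' @param genome_sims Optional precomputed output of [all_pairs_gcr()]
#'   (skips the genome-alignment stage).
#' @param out_dir Optional directory; when given, every intermediate is
#'   written (TSV/FASTA/Newick/JSON) together with an echo of `params` and
#'   `seed`.
#' @return List of class `mlsa_select_report`: `screen`, `gene_stage`
#'   (per-gene funnel outcome), `primer_pairs`, `fragments` (per-gene
#'   `multi_alignment`), `genome_sims`, `models`, `ranking`, `selected`,
#'   `combined_model`, `tree` (bootstrapped NJ tree of the concatenated
#'   selected fragments, or NULL), `support` (its `support_summary`),
#'   `params`, `seed`.
#' @export
run_select <- function(catalogue, genomes, coords = NULL,
                       params = pipeline_params(), seed,
                       genome_sims = NULL, out_dir = NULL) {
    if (missing(seed)) stop("seed is required")
    taxa <- names(genomes)
    stage <- setNames(rep("screened_out", length(catalogue)),
                      names(catalogue))
    scr <- screen(catalogue, taxa, coords = coords, genomes = genomes,
                  min_len = params$min_len,
                  min_separation = params$min_separation)
    stage[scr$survivors] <- "screened"
    primer_pairs <- list()
    fragments <- list()
    for (g in scr$survivors) {
        aln <- multi_alignment(lapply(names(catalogue[[g]]$seqs), function(tx)
            seq_record(tx, catalogue[[g]]$seqs[[tx]], gapped = TRUE)))
        prof <- window_profile(aln, params$window, params$step)
        regions <- call_regions(prof, params$conserved_threshold,
                                params$min_conserved_windows)
        pairs <- enumerate_primer_pairs(
            aln, regions, primer_len_range = params$primer_len_range,
            product_range = params$product_range,
            max_degeneracy = params$max_degeneracy, name_prefix = g)
        if (length(pairs) == 0L) { stage[g] <- "no_primer_pair"; next }
        best <- pairs[[1]]
        amp_ok <- TRUE
        for (tx in taxa) {
            amp <- insilico_pcr(genomes[[tx]], best)
            if (nrow(amp) != 1L) { amp_ok <- FALSE; break }
        }
        if (!amp_ok) { stage[g] <- "pcr_failed"; next }
        primer_pairs[[g]] <- best
        frag_cols <- (best$fwd$aln_end + 1L):(best$rev$aln_start - 1L)
        m <- aln_matrix(aln)[, frag_cols, drop = FALSE]
        fragments[[g]] <- matrix_to_alignment(m)
        stage[g] <- "fragment_extracted"
    }
    if (length(fragments) == 0L) {
        rep <- structure(list(screen = scr, gene_stage = stage,
                              primer_pairs = primer_pairs,
                              fragments = fragments, genome_sims = NULL,
                              models = NULL, ranking = NULL,
                              selected = character(0),
                              combined_model = NULL, tree = NULL,
                              support = NULL, params = params, seed = seed),
                         class = "mlsa_select_report")
        if (!is.null(out_dir)) write_report(rep, out_dir)
        return(rep)
    }
    if (is.null(genome_sims)) genome_sims <- all_pairs_gcr(genomes, params)
    models <- lapply(names(fragments), function(g) {
        fr <- fragments[[g]]
        seqs <- setNames(lapply(fr$records, `[[`, "seq"), fr$ids)
        fit_quadratic(build_pairs(seqs, genome_sims), gene_label = g)
    })
    names(models) <- names(fragments)
    rk <- rank_genes(models, params$r2_threshold)
    selected <- rk$selected
    stage[selected] <- "selected"
    stage[setdiff(names(fragments), selected)] <- "low_r2"
    combined_model <- NULL
    tree <- NULL
    supp <- NULL
    if (length(selected) >= 1L) {
        concat <- concatenate_alignments(fragments[selected], taxa)
        seqs <- setNames(lapply(concat$records, `[[`, "seq"), concat$ids)
        if (length(selected) >= 1L)
            combined_model <- fit_quadratic(
                build_pairs(seqs, genome_sims),
                gene_label = paste(selected, collapse = "+"))
        if (length(taxa) >= 3L) {
            tree <- bootstrap_support(concat, n_reps = params$n_boot,
                                      seed = seed)
            supp <- support_summary(tree, params$support_threshold)
        }
    }
    rep <- structure(list(screen = scr, gene_stage = stage,
                          primer_pairs = primer_pairs,
                          fragments = fragments,
                          genome_sims = genome_sims,
                          models = models, ranking = rk$ranking,
                          selected = selected,
                          combined_model = combined_model, tree = tree,
                          support = supp, params = params, seed = seed),
                     class = "mlsa_select_report")
    if (!is.null(out_dir)) write_report(rep, out_dir)
    rep
}

#' @export
print.mlsa_select_report <- function(x, ...) {
    cat("<mlsa_select_report>\n  funnel: ")
    print(table(x$gene_stage))
    cat("  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
    if (!is.null(x$combined_model))
        cat(sprintf("  combined model R2 = %.3f\n", x$combined_model$r2))
    invisible(x)
}

write_report <- function(rep, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(rep$screen$verdicts, file.path(out_dir, "screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep$screen$linked_pairs))
        write.table(rep$screen$linked_pairs,
                    file.path(out_dir, "linked_pairs.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = names(rep$gene_stage),
                           stage = unname(rep$gene_stage)),
                file.path(out_dir, "funnel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(rep$primer_pairs) > 0L)
        write_primer_tsv(rep$primer_pairs, file.path(out_dir, "primers.tsv"))
    for (g in names(rep$fragments))
        write_fasta(rep$fragments[[g]],
                    file.path(out_dir, paste0("fragment_", g, ".fasta")))
    if (!is.null(rep$genome_sims))
        write.table(rep$genome_sims, file.path(out_dir, "genome_sims.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep$ranking))
        write.table(rep$ranking, file.path(out_dir, "models.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep$tree))
        write_tree_newick(rep$tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(
        list(params = rep$params, seed = rep$seed,
             selected = rep$selected),
        file.path(out_dir, "run_config.json"), auto_unbox = TRUE,
        digits = NA)
    invisible(out_dir)
}
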