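BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(3L, 4L, 1L, 2L)       # A<->G, C<->T
TV_FIRST  <- c(2L, 1L, 2L, 1L)
TV_SECOND <- c(4L, 3L, 4L, 3L)

int_to_dna <- function(x) paste(BASES[x], collapse = "")
dna_to_int <- function(s) match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
                                BASES)

# one K2P step of branch length d (expected substitutions/site at rate 1),
# per-site rate multipliers, transition/transversion rate ratio kappa
mutate_k2p <- function(x, d, rates, kappa = 2) {
    out <- x
    beta <- 1 / (kappa + 2); alpha <- kappa * beta
    for (r in unique(rates)) {
        if (r <= 0) next
        idx <- which(rates == r)
        dd <- d * r
        e4b <- exp(-4 * beta * dd)
        e2ab <- exp(-2 * (alpha + beta) * dd)
        p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
        p_tv <- 0.25 - 0.25 * e4b          # each of the two targets
        u <- runif(length(idx))
        cur <- x[idx]
        new <- cur
        s1 <- u < p_ts
        new[s1] <- TS_PARTNER[cur[s1]]
        s2 <- u >= p_ts & u < p_ts + p_tv
        new[s2] <- TV_FIRST[cur[s2]]
        s3 <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
        new[s3] <- TV_SECOND[cur[s3]]
        out[idx] <- new
    }
    out
}

#' Simulate an ultrametric (clock-like) tree
#'
#' @param n_taxa Number of tips (>= 3), labelled `t1..tn`.
#' @param shape `"balanced"` (successive halving) or `"coalescent"`
#'   (random coalescent, rescaled).
#' @param seed RNG seed.
#' @param height Root-to-tip height in expected substitutions per site.
#' @return An ultrametric `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, shape = c("balanced", "coalescent"),
                          seed = 1L, height = 0.05) {
    if (n_taxa < 3L) stop("need at least 3 taxa")
    shape <- match.arg(shape)
    set.seed(seed)
    labels <- paste0("t", seq_len(n_taxa))
    if (shape == "coalescent") {
        tr <- ape::rcoal(n_taxa, tip.label = labels)
        depth <- max(ape::node.depth.edgelength(tr))
        tr$edge.length <- tr$edge.length * height / depth
        return(tr)
    }
    # balanced: split the taxon list in halves; node height is proportional
    # to the number of bifurcation levels below it, so all tips sit at 0
    levels_of <- function(k) if (k <= 1L) 0L else
        1L + max(levels_of(ceiling(k / 2)), levels_of(floor(k / 2)))
    max_lev <- levels_of(n_taxa)
    build <- function(lab) {
        k <- length(lab)
        if (k == 1L) return(list(nwk = lab, lev = 0L))
        l <- build(lab[1:ceiling(k / 2)])
        r <- build(lab[(ceiling(k / 2) + 1L):k])
        lev <- 1L + max(l$lev, r$lev)
        h <- height * lev / max_lev
        hl <- height * l$lev / max_lev
        hr <- height * r$lev / max_lev
        list(nwk = sprintf("(%s:%.10f,%s:%.10f)", l$nwk, h - hl,
                           r$nwk, h - hr), lev = lev)
    }
    ape::read.tree(text = paste0(build(labels)$nwk, ";"))
}

#' Default candidate-gene panel for a simulated world
#'
#' Eight candidate genes: three well-behaved MLSA markers (long,
#' single-copy, clock-like, with invariant primer flanks around a
#' hypervariable core), plus five engineered failures -- a short gene, a
#' gene with a 90%-identical paralogue planted in the genome, a gene
#' missing from one taxon, a flagged aminoacyl-tRNA-synthetase gene, and a
#' tree-discordant gene whose evolved sequences are exchanged among taxa
#' (a recombination-like history: its fragment similarity cannot predict
#' genome relatedness).
#'
#' @return data.frame understood by [evolve_genomes()]; columns `name`,
#'   `length`, `rate_multiplier` (applied outside the flanks),
#'   `planted_flanks` (`"both"`, `"left"`, `"none"`), `decoy_paralog`,
#'   `missing_taxon` (label or NA), `flags`, `scrambled`, `gap_before`
#'   (NA = equal split), `expected_fate`.
#' @export
default_gene_panel <- function() {
    data.frame(
        name = c("marA", "marB", "marC", "shoD", "dupE", "misF", "aaG",
                 "errH"),
        length = c(1000L, 1000L, 1000L, 500L, 1000L, 1000L, 1000L, 1000L),
        rate_multiplier = c(6, 6, 6, 6, 1, 6, 6, 6),
        planted_flanks = c("both", "both", "both", "both", "both", "both",
                           "both", "both"),
        decoy_paralog = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                          FALSE),
        missing_taxon = c(NA, NA, NA, NA, NA, "t2", NA, NA),
        flags = c("", "", "", "", "", "", "aaRS", ""),
        scrambled = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE),
        gap_before = NA_integer_,
        expected_fate = c("selected", "selected", "selected", "length",
                          "copy_number", "ubiquity", "excluded",
                          "low_r2"),
        stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_taxa Number of taxa.
#' @param genome_length Genome size in bp.
#' @param genes Gene panel data.frame (see [default_gene_panel()]).
#' @param tree_shape,tree_height Passed to [simulate_tree()].
#' @param accessory_fraction Fraction of each intergenic block replaced by
#'   fresh per-lineage random sequence (unalignable pan-genome content).
#' @param kappa K2P transition/transversion rate ratio.
#' @param flank_len Invariant primer-flank length in bp.
#' @param seed Mandatory seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 10L, genome_length = 100000L,
                       genes = default_gene_panel(),
                       tree_shape = "balanced", tree_height = 0.05,
                       accessory_fraction = 0.35, kappa = 2,
                       flank_len = 50L, seed) {
    if (missing(seed)) stop("seed is mandatory")
    if (any(genes$rate_multiplier < 0)) stop("rate multipliers must be >= 0")
    gene_total <- sum(genes$length)
    if (gene_total >= genome_length)
        stop("genes (", gene_total, " bp) do not fit in genome_length")
    structure(list(n_taxa = n_taxa, genome_length = genome_length,
                   genes = genes, tree_shape = tree_shape,
                   tree_height = tree_height,
                   accessory_fraction = accessory_fraction, kappa = kappa,
                   flank_len = flank_len, seed = seed),
              class = "sim_config")
}

# genome layout: alternating intergenic blocks and genes, each intergenic
# block carrying a central accessory sub-segment; the dupE decoy (if any)
# sits in the backbone of the final block
build_layout <- function(config) {
    genes <- config$genes
    K <- nrow(genes)
    gene_total <- sum(genes$length)
    decoy_genes <- genes$name[genes$decoy_paralog]
    decoy_total <- if (length(decoy_genes))
        genes$length[genes$name == decoy_genes[1]] else 0L
    inter_total <- config$genome_length - gene_total
    fixed <- !is.na(genes$gap_before)
    fixed_total <- sum(genes$gap_before[fixed])
    n_free <- K + 1L - sum(fixed)
    free_len <- floor((inter_total - fixed_total - decoy_total) / n_free)
    if (free_len < 40L)
        stop("genome_length leaves too little intergenic space; ",
             "increase it or drop genes")
    segs <- list()
    pos <- 1L
    add <- function(type, name, len, rate) {
        if (len <= 0L) return()
        segs[[length(segs) + 1L]] <<- data.frame(
            type = type, name = name, start = pos, end = pos + len - 1L,
            rate = rate)
        pos <<- pos + len
    }
    add_inter <- function(len, decoy_name = NA_character_,
                          decoy_len = 0L) {
        acc <- round(config$accessory_fraction * (len - decoy_len))
        back <- len - acc - decoy_len
        if (back < 0L) stop("intergenic block too small for the decoy")
        b1 <- floor(back / 2); b2 <- back - b1
        add("backbone", "", b1, 1)
        if (decoy_len > 0L) add("decoy", decoy_name, decoy_len, 1)
        add("accessory", "", acc, 1)
        add("backbone", "", b2, 1)
    }
    for (i in seq_len(K)) {
        gap <- if (fixed[i]) genes$gap_before[i] else free_len
        add_inter(gap)
        g <- genes[i, ]
        fl <- config$flank_len
        if (g$planted_flanks == "both") {
            # invariant flanks at [1, fl] and [L-200+1-fl .. L-200] leave a
            # variable 3' tail and keep products inside 600-900 bp
            core_end <- g$length - 150L - fl
            add("gene_flank", g$name, fl, 0)
            add("gene_core", g$name, max(0L, core_end - fl), g$rate_multiplier)
            add("gene_flank", g$name, fl, 0)
            add("gene_core", g$name, 150L, g$rate_multiplier)
        } else if (g$planted_flanks == "left") {
            add("gene_flank", g$name, fl, 0)
            add("gene_core", g$name, g$length - fl, g$rate_multiplier)
        } else {
            add("gene_core", g$name, g$length, g$rate_multiplier)
        }
    }
    tail_len <- config$genome_length - (pos - 1L)
    decoy_len <- if (length(decoy_genes)) {
        genes$length[genes$name == decoy_genes[1]]
    } else 0L
    add_inter(tail_len, if (decoy_len) decoy_genes[1] else NA_character_,
              decoy_len)
    do.call(rbind, segs)
}

#' Evolve a synthetic genome world along a known tree
#'
#' Draws a uniform-random ancestral genome, evolves it along the tree
#' under the K2P substitution model with per-segment rate multipliers
#' (invariant primer flanks have rate 0; no indels inside genes, so gene
#' alignments are exact by construction), refreshes accessory segments
#' with independent random sequence in every tip (pan-genome content that
#' depresses genome coverage without touching conserved-region identity),
#' plants decoy paralogues at ~90% ancestral identity, and removes genes
#' marked missing from their target taxon.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_world`: `genomes` (named list of
#'   [seq_record()]), `catalogue` (a `gene_catalogue`), `alignments`
#'   (named list of `multi_alignment` per gene), `coords` (gene coordinate
#'   data.frame), `truth` (tree, newick, pairwise tip distances, layout,
#'   flank/decoy coordinates, per-gene info), `config`.
#' @export
evolve_genomes <- function(config) {
    set.seed(config$seed)
    tree <- simulate_tree(config$n_taxa, config$tree_shape,
                          seed = config$seed, height = config$tree_height)
    layout <- build_layout(config)
    G <- config$genome_length
    rates <- numeric(G)
    for (i in seq_len(nrow(layout)))
        rates[layout$start[i]:layout$end[i]] <- layout$rate[i]
    anc <- sample.int(4L, G, replace = TRUE)
    # decoy paralogue: ancestral copy of its gene with ~10% substitutions
    decoy_rows <- which(layout$type == "decoy")
    for (dr in decoy_rows) {
        gname <- layout$name[dr]
        gsegs <- layout[layout$name == gname &
                        grepl("^gene", layout$type), , drop = FALSE]
        gene_anc <- unlist(lapply(seq_len(nrow(gsegs)), function(i)
            anc[gsegs$start[i]:gsegs$end[i]]))
        nmut <- round(0.10 * length(gene_anc))
        at <- sample.int(length(gene_anc), nmut)
        gene_anc[at] <- ((gene_anc[at] - 1L + sample.int(3L, nmut,
                                                         replace = TRUE)) %% 4L) + 1L
        span <- layout$start[dr]:layout$end[dr]
        anc[span] <- gene_anc[seq_along(span)]
    }
    # evolve down the main tree
    edge_order <- reorder(tree, "cladewise")$edge
    edge_len <- tree$edge.length[match(paste(edge_order[, 1], edge_order[, 2]),
                                       paste(tree$edge[, 1], tree$edge[, 2]))]
    nnode <- max(tree$edge)
    seqs <- vector("list", nnode)
    root <- config$n_taxa + 1L
    seqs[[root]] <- anc
    for (e in seq_len(nrow(edge_order))) {
        p <- edge_order[e, 1]; ch <- edge_order[e, 2]
        seqs[[ch]] <- mutate_k2p(seqs[[p]], edge_len[e], rates, config$kappa)
    }
    tips <- setNames(seqs[seq_len(config$n_taxa)], tree$tip.label)
    # scrambled genes: exchange the evolved per-taxon gene sequences among
    # taxa by a fixed interleaving permutation (a recombination/HGT-like
    # history), so the fragment's similarity structure is decoupled from
    # the genome's while its variability profile stays marker-like
    scr <- config$genes$name[config$genes$scrambled]
    if (length(scr) > 0L) {
        n <- config$n_taxa
        perm <- c(seq(1L, n, by = 2L), seq(2L, n, by = 2L))
        labs <- tree$tip.label
        for (gname in scr) {
            gsegs <- layout[layout$name == gname &
                            grepl("^gene", layout$type), , drop = FALSE]
            sites <- unlist(lapply(seq_len(nrow(gsegs)), function(i)
                gsegs$start[i]:gsegs$end[i]))
            orig <- lapply(labs, function(tx) tips[[tx]][sites])
            for (k in seq_len(n))
                tips[[labs[k]]][sites] <- orig[[perm[k]]]
        }
    }
    # per-tip post-processing: fresh accessory content, removed genes
    acc_rows <- which(layout$type == "accessory")
    for (tx in names(tips)) {
        for (ar in acc_rows) {
            span <- layout$start[ar]:layout$end[ar]
            tips[[tx]][span] <- sample.int(4L, length(span), replace = TRUE)
        }
    }
    miss <- config$genes[!is.na(config$genes$missing_taxon), , drop = FALSE]
    for (i in seq_len(nrow(miss))) {
        tx <- miss$missing_taxon[i]
        gsegs <- layout[layout$name == miss$name[i] &
                        grepl("^gene", layout$type), , drop = FALSE]
        for (j in seq_len(nrow(gsegs))) {
            span <- gsegs$start[j]:gsegs$end[j]
            tips[[tx]][span] <- sample.int(4L, length(span), replace = TRUE)
        }
    }
    genomes <- lapply(names(tips), function(tx)
        seq_record(tx, int_to_dna(tips[[tx]])))
    names(genomes) <- names(tips)
    # catalogue, alignments, coordinates
    gene_tbl <- do.call(rbind, lapply(config$genes$name, function(gname) {
        gsegs <- layout[layout$name == gname &
                        grepl("^gene", layout$type), , drop = FALSE]
        data.frame(gene = gname, start = min(gsegs$start),
                   end = max(gsegs$end))
    }))
    entries <- lapply(seq_len(nrow(config$genes)), function(i) {
        g <- config$genes[i, ]
        taxa <- names(tips)
        if (!is.na(g$missing_taxon)) taxa <- setdiff(taxa, g$missing_taxon)
        row <- gene_tbl[gene_tbl$gene == g$name, ]
        seqs_g <- lapply(setNames(taxa, taxa), function(tx)
            substr(genomes[[tx]]$seq, row$start, row$end))
        flags <- if (nzchar(g$flags))
            strsplit(g$flags, ",", fixed = TRUE)[[1]] else character(0)
        list(gene = g$name, category = "", seqs = seqs_g, flags = flags)
    })
    catalogue <- gene_catalogue(entries)
    alignments <- lapply(catalogue, function(e) {
        if (length(e$seqs) < 2L) return(NULL)
        multi_alignment(lapply(names(e$seqs), function(tx)
            seq_record(tx, e$seqs[[tx]], gapped = TRUE)))
    })
    names(alignments) <- names(catalogue)
    coords <- do.call(rbind, lapply(seq_len(nrow(gene_tbl)), function(i)
        data.frame(taxon = names(tips), gene = gene_tbl$gene[i],
                   start = gene_tbl$start[i], end = gene_tbl$end[i],
                   strand = "+")))
    flanks <- layout[layout$type == "gene_flank", , drop = FALSE]
    decoys <- layout[layout$type == "decoy", , drop = FALSE]
    truth <- list(tree = tree, newick = ape::write.tree(tree),
                  distances = cophenetic(tree),
                  layout = layout, gene_info = cbind(config$genes, gene_tbl[
                      match(config$genes$name, gene_tbl$gene),
                      c("start", "end")]),
                  flank_coords = flanks, decoy_coords = decoys)
    structure(list(genomes = genomes, catalogue = catalogue,
                   alignments = alignments, coords = coords, truth = truth,
                   config = config),
              class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
    cat("<sim_world> ", length(x$genomes), " genomes of ",
        x$config$genome_length, " bp, ", nrow(x$config$genes),
        " candidate genes (seed ", x$config$seed, ")\n", sep = "")
    invisible(x)
}

#' Screening fixture with known pass/fail labels
#'
#' A small simulated world whose catalogue contains, by construction, a
#' short gene, a duplicated gene, a gene missing from one taxon, a flagged
#' gene, a closely linked gene pair, and clean controls -- each labelled
#' with the criterion it must fail (`expected_fate`).
#'
#' @param seed RNG seed.
#' @param n_taxa,genome_length World size.
#' @return A `sim_world`; `$config$genes$expected_fate` holds the labels.
#' @export
make_screen_fixture <- function(seed, n_taxa = 6L, genome_length = 120000L) {
    genes <- data.frame(
        name = c("okA", "okB", "shoC", "dupD", "misE", "ribF", "linG",
                 "linH"),
        length = c(1000L, 1000L, 500L, 1000L, 1000L, 1000L, 1000L, 1000L),
        rate_multiplier = c(4, 4, 4, 1, 4, 4, 4, 4),
        planted_flanks = "both",
        decoy_paralog = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                          FALSE),
        missing_taxon = c(NA, NA, NA, NA, "t3", NA, NA, NA),
        flags = c("", "", "", "", "", "ribosomal", "", ""),
        scrambled = FALSE,
        gap_before = c(NA, NA, NA, NA, NA, NA, NA, 500L),
        expected_fate = c("pass", "pass", "length", "copy_number",
                          "ubiquity", "excluded", "pass_linked",
                          "pass_linked"),
        stringsAsFactors = FALSE)
    evolve_genomes(sim_config(n_taxa = n_taxa,
                              genome_length = genome_length, genes = genes,
                              tree_height = 0.04, seed = seed))
}

#' Write a simulated world to disk
#'
#' @param world A `sim_world`.
#' @param out_dir Output directory (created): `genomes/*.fa`,
#'   `genes/*.aln.fasta`, `coords.tsv`, `truth.json`, `config.json`.
#' @return `out_dir`, invisibly.
#' @export
write_world <- function(world, out_dir) {
    dir.create(file.path(out_dir, "genomes"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)
    for (tx in names(world$genomes))
        write_fasta(list(world$genomes[[tx]]),
                    file.path(out_dir, "genomes", paste0(tx, ".fa")))
    for (g in names(world$alignments)) {
        if (is.null(world$alignments[[g]])) next
        write_fasta(world$alignments[[g]],
                    file.path(out_dir, "genes", paste0(g, ".aln.fasta")))
    }
    write.table(world$coords, file.path(out_dir, "coords.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- world$truth
    jsonlite::write_json(
        list(newick = truth$newick,
             distances = as.data.frame(as.table(truth$distances)),
             gene_info = truth$gene_info,
             flank_coords = truth$flank_coords,
             decoy_coords = truth$decoy_coords),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    cfg <- world$config
    cfg_list <- unclass(cfg)
    jsonlite::write_json(cfg_list, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(out_dir)
}
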