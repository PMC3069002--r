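# Independent brute-force oracles and shared fixtures. Everything here is
# deliberately naive: enumerate, count columns, or recurse -- never reuse
# the package's own algorithms.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

rc_plain <- function(s) chartr("ACGT", "TGCA",
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))

# enumerate maximal exact matches per diagonal via run-length encoding,
# then keep those whose matched substring occurs exactly once in each
# sequence (overlap-aware counting via Biostrings)
bf_mums_strand <- function(r, q, min_len) {
    rcv <- strsplit(r, "", fixed = TRUE)[[1]]
    qcv <- strsplit(q, "", fixed = TRUE)[[1]]
    nr <- length(rcv); nq <- length(qcv)
    rows <- list()
    for (off in (-(nq - 1)):(nr - 1)) {
        i0 <- max(1L, 1L + off)
        j0 <- i0 - off
        len <- min(nr - i0, nq - j0) + 1L
        if (len < min_len) next
        eq <- rcv[i0:(i0 + len - 1L)] == qcv[j0:(j0 + len - 1L)]
        rl <- rle(eq)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1L
        for (k in which(rl$values & rl$lengths >= min_len))
            rows[[length(rows) + 1L]] <- c(i0 + starts[k] - 1L,
                                           j0 + starts[k] - 1L,
                                           rl$lengths[k])
    }
    if (length(rows) == 0L)
        return(data.frame(ref_start = integer(0), query_start = integer(0),
                          length = integer(0)))
    m <- as.data.frame(do.call(rbind, rows))
    names(m) <- c("ref_start", "query_start", "length")
    keep <- vapply(seq_len(nrow(m)), function(i) {
        pat <- substr(r, m$ref_start[i], m$ref_start[i] + m$length[i] - 1L)
        Biostrings::countPattern(pat, r) == 1L &&
            Biostrings::countPattern(pat, q) == 1L
    }, logical(1))
    m[keep, , drop = FALSE]
}

bf_mums <- function(r, q, min_len) {
    fwd <- bf_mums_strand(r, q, min_len)
    rev <- bf_mums_strand(r, rc_plain(q), min_len)
    out <- rbind(if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
                 if (nrow(rev)) cbind(rev, strand = "-") else NULL)
    if (is.null(out))
        out <- data.frame(ref_start = integer(0), query_start = integer(0),
                          length = integer(0), strand = character(0))
    out[order(out$strand, out$ref_start, out$query_start), , drop = FALSE]
}

canon_mums <- function(m) {
    rownames(m) <- NULL
    m[order(m$strand, m$ref_start, m$query_start, m$length),
      c("ref_start", "query_start", "length", "strand")]
}

# brute-force K2P from explicit transition/transversion counting
bf_k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)

# additive matrix of a random tree with strictly positive branch lengths
random_additive_tree <- function(n, seed) {
    set.seed(seed)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 2))
    list(tree = tr, dm = cophenetic(tr))
}

# shared small simulated worlds, built once per test run; 10 taxa give the
# pairwise-distance diversity the regression stage needs, 50 kb genomes
# keep the genome-alignment stage fast
small_world <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- evolve_genomes(sim_config(n_taxa = 10L,
                                                genome_length = 50000L,
                                                seed = 11L))
        cache
    }
})

small_world_gcr <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- all_pairs_gcr(small_world()$genomes)
        cache
    }
})

screen_fixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- make_screen_fixture(seed = 7L)
        cache
    }
})

make_aln <- function(seqs) {
    multi_alignment(lapply(names(seqs), function(id)
        seq_record(id, seqs[[id]], gapped = TRUE)))
}
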