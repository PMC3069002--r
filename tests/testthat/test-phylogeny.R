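# build a pair of aligned sequences with exactly nP transitions and nQ
# transversions over n sites
pq_pair <- function(n, nP, nQ) {
    a <- rep("A", n)
    b <- a
    if (nP > 0) b[seq_len(nP)] <- "G"                      # A->G transition
    if (nQ > 0) b[nP + seq_len(nQ)] <- "T"                 # A->T transversion
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

test_that("K2P distance matches the closed form on a (P,Q) grid", {
    expect_equal(k2p_distance("ACGT", "ACGT"), 0)
    p <- pq_pair(100, 10, 5)
    expect_equal(k2p_distance(p$a, p$b), bf_k2p(0.10, 0.05),
                 tolerance = 1e-9)
    expect_equal(bf_k2p(0.10, 0.05), 0.170181, tolerance = 1e-6)
    for (P in c(0, 0.05, 0.1, 0.2)) {
        for (Q in c(0, 0.05, 0.1, 0.2)) {
            if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) next
            p <- pq_pair(200, 200 * P, 200 * Q)
            expect_equal(k2p_distance(p$a, p$b), bf_k2p(P, Q),
                         tolerance = 1e-9)
        }
    }
    sat <- pq_pair(100, 50, 0)
    expect_error(k2p_distance(sat$a, sat$b), "saturated")
    # symmetry
    p <- pq_pair(150, 12, 9)
    expect_equal(k2p_distance(p$a, p$b), k2p_distance(p$b, p$a))
})

test_that("gapped and ambiguous columns use pairwise deletion", {
    # gap and N columns are excluded from the comparable set
    a <- "ACGTACGTAC-TNA"
    b <- "ACGTACGAACGT-A"
    # comparable columns: positions 1..10, 12, 14 -> 12 sites, one
    # transversion at position 8
    a2 <- "ACGTACGTACTA"; b2 <- "ACGTACGAACTA"
    expect_equal(k2p_distance(a, b), k2p_distance(a2, b2))
})

test_that("K2P matrix agrees with an independent implementation", {
    set.seed(81)
    seqs <- setNames(lapply(1:5, function(i) random_dna(400)),
                     paste0("t", 1:5))
    # make them related so distances are finite
    base <- strsplit(seqs[[1]], "")[[1]]
    for (i in 2:5) {
        ch <- base
        at <- sample(400, 30 * i)
        ch[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
        seqs[[i]] <- paste(ch, collapse = "")
    }
    aln <- make_aln(seqs)
    d1 <- k2p_matrix(aln)
    bin <- ape::as.DNAbin(lapply(seqs, function(s)
        tolower(strsplit(s, "")[[1]])))
    d2 <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
    expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-9)
})

test_that("NJ recovers a 4-taxon additive tree exactly", {
    taxa <- c("A", "B", "C", "D")
    dm <- matrix(c(0, 3, 5, 6,
                   3, 0, 6, 7,
                   5, 6, 0, 7,
                   6, 7, 7, 0), 4, 4, dimnames = list(taxa, taxa))
    tr <- nj_tree(dm)
    expect_equal(as.matrix(cophenetic(tr))[taxa, taxa], dm,
                 tolerance = 1e-9)
    # topology: (A,B) vs (C,D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::read.tree(
        text = "((A:1,B:2):1,C:3,D:4);")), 0, ignore_attr = TRUE)
    expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ path distances reproduce random additive matrices", {
    for (seed in 1:20) {
        n <- sample(4:10, 1)
        ad <- random_additive_tree(n, seed)
        tr <- nj_tree(ad$dm)
        expect_equal(as.matrix(cophenetic(tr))[rownames(ad$dm),
                                               colnames(ad$dm)],
                     ad$dm, tolerance = 1e-8)
        expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ad$tree)),
                     0, ignore_attr = TRUE)
    }
})

test_that("negative NJ branches are clamped without breaking totals", {
    # a slightly non-additive matrix that induces a negative branch
    dm <- matrix(c(0, 0.1, 0.5, 0.52,
                   0.1, 0, 0.5, 0.52,
                   0.5, 0.5, 0, 0.01,
                   0.52, 0.52, 0.01, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
    tr <- nj_tree(dm)
    expect_true(all(tr$edge.length >= 0))
})

test_that("constructed clade signal earns full bootstrap support", {
    set.seed(82)
    blockA <- strrep("A", 60); blockG <- strrep("G", 60)
    shared <- random_dna(400)
    mut <- function(s, k) {
        ch <- strsplit(s, "")[[1]]
        at <- sample(length(ch), k)
        ch[at] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
        paste(ch, collapse = "")
    }
    aln <- make_aln(list(
        t1 = paste0(blockA, mut(shared, 12)),
        t2 = paste0(blockA, mut(shared, 12)),
        t3 = paste0(blockG, mut(shared, 12)),
        t4 = paste0(blockG, mut(shared, 12))))
    tr <- bootstrap_support(aln, n_reps = 200, seed = 9)
    supp <- attr(tr, "supports")
    expect_length(supp, 1L)          # one internal edge in a 4-taxon tree
    expect_gt(supp[[1]], 95)
})

test_that("bootstrap supports are reproducible from the seed", {
    w <- small_world()
    aln <- w$alignments[["marA"]]
    t1 <- bootstrap_support(aln, n_reps = 50, seed = 123)
    t2 <- bootstrap_support(aln, n_reps = 50, seed = 123)
    expect_identical(attr(t1, "supports"), attr(t2, "supports"))
    expect_error(bootstrap_support(aln, n_reps = 50), "seed")
})

test_that("support summaries count strictly above the threshold", {
    s <- support_summary(c(70, 80, 60, 90), threshold = 65)
    expect_equal(s$n_above_threshold, 3L)
    expect_equal(s$percent_above, 75)
    expect_equal(support_summary(rep(100, 7))$percent_above, 100)
    expect_equal(support_summary(rep(0, 7))$percent_above, 0)
    # boundary value is not counted
    expect_equal(support_summary(c(65, 66))$n_above_threshold, 1L)
})

test_that("chi-square support comparison matches hand computation", {
    mk <- function(above, total) support_summary(
        c(rep(100, above), rep(0, total - above)), threshold = 65)
    same <- compare_support(mk(40, 100), mk(40, 100))
    expect_equal(same$chi2, 0)
    expect_equal(same$p_value, 1)
    cs <- compare_support(mk(81, 100), mk(68, 100))
    # hand-computed Pearson chi-square: N(ad-bc)^2 / (r1 r2 c1 c2)
    bf <- 200 * (81 * 32 - 19 * 68)^2 / (100 * 100 * 149 * 51)
    expect_equal(cs$chi2, bf, tolerance = 1e-9)
    expect_equal(cs$chi2, 4.4479, tolerance = 1e-4)
    expect_equal(cs$p_value, 0.0349, tolerance = 1e-2)
    extreme <- compare_support(mk(100, 100), mk(0, 100))
    expect_lt(extreme$p_value, 1e-20)
    expect_error(compare_support(mk(100, 100), mk(100, 100)),
                 "zero marginal")
})
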