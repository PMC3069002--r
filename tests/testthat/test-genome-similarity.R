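test_that("a sequence against itself yields one full-length MUM", {
    set.seed(61)
    s <- random_dna(200)
    m <- find_mums(s, s, 12)
    fwd <- m[m$strand == "+", ]
    expect_equal(nrow(fwd), 1L)
    expect_equal(fwd$ref_start, 1L)
    expect_equal(fwd$length, 200L)
})

test_that("reverse-complement-only homology appears on the minus strand", {
    set.seed(62)
    s <- random_dna(300)
    m <- find_mums(s, rc_plain(s), 12)
    expect_true(all(m[m$length == 300, "strand"] == "-"))
    expect_equal(max(m$length), 300L)
})

test_that("MUM finder agrees exactly with the brute-force enumerator", {
    set.seed(63)
    for (i in 1:25) {
        n1 <- sample(80:400, 1); n2 <- sample(80:400, 1)
        base <- random_dna(max(n1, n2))
        # make the pair related so matches actually occur
        r <- substr(base, 1, n1)
        qc <- strsplit(substr(base, 1, n2), "")[[1]]
        at <- sample(length(qc), round(0.05 * length(qc)))
        qc[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
        q <- paste(qc, collapse = "")
        expect_equal(canon_mums(find_mums(r, q, 12)),
                     canon_mums(bf_mums(r, q, 12)),
                     ignore_attr = TRUE)
    }
})

test_that("anchor chaining follows the gap, diagonal and size rules", {
    mk <- function(rs, qs, len) data.frame(ref_start = rs, query_start = qs,
                                           length = len, strand = "+")
    # two 30 bp matches on one diagonal 100 bp apart -> one cluster (60 >= 40)
    m <- rbind(mk(1, 1, 30), mk(131, 131, 30))
    cl <- cluster_matches(m)
    expect_length(cl, 1L)
    expect_equal(nrow(cl[[1]]), 2L)
    # a single 30 bp match is discarded (< minCluster 40)
    expect_length(cluster_matches(mk(1, 1, 30)), 0L)
    # matches 300 bp apart exceed maxGap 250 -> separate clusters
    m2 <- rbind(mk(1, 1, 50), mk(351, 351, 50))
    expect_length(cluster_matches(m2), 2L)
    # excessive diagonal shift breaks the chain
    m3 <- rbind(mk(1, 1, 50), mk(151, 251, 50))
    expect_length(cluster_matches(m3), 2L)
})

test_that("gap closing fuses anchors and matches an alignment oracle", {
    set.seed(64)
    seg <- random_dna(1000)
    m <- find_mums(seg, seg, 12)
    cl <- cluster_matches(m[m$strand == "+", ])
    rg <- close_gaps(seg, seg, cl[[1]])
    expect_equal(nrow(rg), 1L)
    expect_equal(rg$identity, 100)
    expect_equal(rg$ref_start, 1L)
    expect_equal(rg$ref_end, 1000L)

    # two anchors separated by a gap with substitutions: identity equals
    # the direct global-alignment identity of the whole span
    a1 <- random_dna(400); a2 <- random_dna(400)
    gap_r <- random_dna(100)
    gc <- strsplit(gap_r, "")[[1]]
    at <- sample(100, 10)
    gc[at] <- vapply(gc[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    ref <- paste0(a1, gap_r, a2)
    qry <- paste0(a1, paste(gc, collapse = ""), a2)
    mm <- find_mums(ref, qry, 12)
    cl <- cluster_matches(mm[mm$strand == "+", ])
    rg <- close_gaps(ref, qry, cl[[1]])
    expect_equal(nrow(rg), 1L)
    bf_ident <- 100 * mean(strsplit(ref, "")[[1]] == strsplit(qry, "")[[1]])
    expect_equal(rg$identity, bf_ident, tolerance = 1e-9)

    # a 5 kb unrelated insertion splits the cluster into two regions
    ref2 <- paste0(a1, a2)
    qry2 <- paste0(a1, random_dna(5000), a2)
    # chain across the insertion (permissive gap/diagonal limits) so the
    # breaklen rule inside gap closing is what splits the region
    mm2 <- find_mums(ref2, qry2, 12)
    cl2 <- cluster_matches(mm2[mm2$strand == "+", ], max_gap = 6000,
                           diag_factor = 2)
    rg2 <- close_gaps(ref2, qry2, cl2[[1]])
    expect_equal(nrow(rg2), 2L)
})

test_that("overlap resolution splits shared reference spans at the midpoint", {
    rg <- data.frame(ref_start = c(1, 81), ref_end = c(100, 180),
                     query_start = c(1, 81), query_end = c(100, 180),
                     length = c(100, 100), matched = c(95, 99),
                     identity = c(95, 99))
    out <- resolve_overlaps(rg)
    expect_equal(out$ref_start, c(1, 91))
    expect_equal(out$ref_end, c(90, 180))
    # disjoint regions pass through unchanged
    rg2 <- data.frame(ref_start = c(1, 201), ref_end = c(100, 300),
                      query_start = c(1, 201), query_end = c(100, 300),
                      length = c(100, 100), matched = c(90, 90),
                      identity = c(90, 90))
    expect_equal(resolve_overlaps(rg2)$ref_start, c(1, 201))
    # identical duplicates collapse to one
    expect_equal(nrow(resolve_overlaps(rg2[c(1, 1), ])), 1L)
})

test_that("weighted identity follows the length-weighted mean", {
    rg <- data.frame(ref_start = c(1, 200), ref_end = c(100, 499),
                     length = c(100, 300), matched = c(90, 294),
                     identity = c(90, 98))
    expect_equal(sum(rg$identity * rg$length) / sum(rg$length), 96)
    # invariant to splitting a region into two halves
    rg_split <- data.frame(length = c(100, 150, 150),
                           identity = c(90, 98, 98))
    expect_equal(with(rg_split, sum(identity * length) / sum(length)), 96)
})

test_that("conserved similarity of identical genomes is 100 at full coverage", {
    set.seed(65)
    g <- random_dna(3000)
    cs <- conserved_similarity(g, g)
    expect_equal(cs$gcr_similarity, 100)
    expect_equal(cs$covered_fraction_ref, 1)
    expect_equal(cs$covered_fraction_query, 1)
})

test_that("similarity tracks a known substitution rate", {
    set.seed(66)
    g <- random_dna(20000)
    ch <- strsplit(g, "")[[1]]
    at <- sample(length(ch), round(0.02 * length(ch)))
    ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    mut <- paste(ch, collapse = "")
    cs <- conserved_similarity(g, mut)
    expect_equal(cs$gcr_similarity, 98, tolerance = 0.3 / 98)
    expect_gt(cs$covered_fraction_ref, 0.98)
})

test_that("swap-merged similarity is nearly symmetric", {
    set.seed(67)
    g <- random_dna(10000)
    ch <- strsplit(g, "")[[1]]
    at <- sample(length(ch), 300)
    ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    h <- paste(c(ch[1:6000], strsplit(random_dna(1500), "")[[1]],
                 ch[6001:10000]), collapse = "")
    s_ab <- conserved_similarity(g, h)$gcr_similarity
    s_ba <- conserved_similarity(h, g)$gcr_similarity
    expect_lt(abs(s_ab - s_ba), 0.5)
})

test_that("no homology yields an empty, flagged result", {
    cs <- conserved_similarity(strrep("A", 500), strrep("G", 500))
    expect_true(is.na(cs$gcr_similarity))
    expect_equal(cs$n_regions, 0L)
    expect_equal(cs$covered_fraction_ref, 0)
})
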