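test_that("degenerate consensus uses minimal IUPAC codes", {
    aln <- make_aln(list(a = "AAA", b = "AGC", c = "AGT", d = "AAG"))
    # columns: {A}, {A,G}, {A,C,G,T}
    expect_equal(consensus_degenerate(aln, 1, 3), "ARN")
    aln2 <- make_aln(list(a = "ACGTC", b = "ACGTG"))
    expect_equal(consensus_degenerate(aln2, 1, 4), "ACGT")
    expect_equal(consensus_degenerate(aln2, 5, 5), "S")
    gapped <- make_aln(list(a = "AC-T", b = "ACGT"))
    expect_error(consensus_degenerate(gapped, 1, 4), "gap.*a")
})

test_that("degeneracy multiplies IUPAC alternative counts", {
    expect_equal(degeneracy("GGHAAGGTSACSCCNAAGGG"), 48)  # 3*2*2*4
    expect_equal(degeneracy("ACGT"), 1)
    expect_equal(degeneracy("NN"), 16)
    expect_equal(degeneracy("GAANCGCTGDCCRCCGAACTG"), 24) # 4*3*2
    expect_error(degeneracy("ACXG"), "illegal")
})

test_that("consensus degeneracy is 1 exactly for invariant slices", {
    set.seed(31)
    for (rep in 1:10) {
        s <- random_dna(30)
        aln <- make_aln(list(a = s, b = s, c = s))
        expect_equal(degeneracy(consensus_degenerate(aln, 3, 20)), 1)
        mut <- strsplit(s, "")[[1]]
        mut[7] <- setdiff(c("A", "C", "G", "T"), mut[7])[1]
        aln2 <- make_aln(list(a = s, b = paste(mut, collapse = "")))
        expect_gt(degeneracy(consensus_degenerate(aln2, 3, 20)), 1)
    }
})

# an alignment engineered with conserved flanks around a hypervariable core
flanked_alignment <- function(n_taxa = 6, left = 50, core = 700, right = 50,
                              seed = 33) {
    set.seed(seed)
    lf <- random_dna(left)
    rf <- random_dna(right)
    seqs <- setNames(lapply(seq_len(n_taxa), function(i)
        paste0(lf, random_dna(core), rf)), paste0("t", seq_len(n_taxa)))
    make_aln(seqs)
}

test_that("primer pairs span the hypervariable block between conserved flanks", {
    aln <- flanked_alignment()
    prof <- window_profile(aln)
    reg <- call_regions(prof)
    expect_equal(reg$kind[c(1, nrow(reg))], c("conserved", "conserved"))
    pairs <- enumerate_primer_pairs(aln, reg, product_range = c(600, 900))
    expect_gt(length(pairs), 0)
    best <- pairs[[1]]
    expect_lte(best$fwd$aln_end, 50)
    expect_gte(best$rev$aln_start, 751)
    expect_true(all(best$expected_product_range >= 600 &
                    best$expected_product_range <= 900))
    # sorted by total degeneracy
    deg <- vapply(pairs, function(p) p$fwd$degeneracy + p$rev$degeneracy,
                  numeric(1))
    expect_true(!is.unsorted(deg))
})

test_that("a single conserved region yields no primer pair", {
    set.seed(34)
    lf <- random_dna(60)
    seqs <- setNames(lapply(1:6, function(i) paste0(lf, random_dna(740))),
                     paste0("t", 1:6))
    aln <- make_aln(seqs)
    reg <- call_regions(window_profile(aln))
    expect_equal(sum(reg$kind == "conserved"), 1L)
    expect_length(enumerate_primer_pairs(aln, reg), 0)
})

test_that("max_degeneracy = 1 on variable flanks yields no pair", {
    aln <- flanked_alignment(seed = 35)
    # corrupt the flanks slightly so no invariant window of >= 17 nt remains
    m <- do.call(rbind, lapply(aln$records, function(r) strsplit(r$seq, "")[[1]]))
    rownames(m) <- aln$ids
    for (j in seq(1, 50, by = 10)) m[1, j] <- setdiff(c("A","C","G","T"), m[2, j])[1]
    for (j in seq(751, 800, by = 10)) m[2, j] <- setdiff(c("A","C","G","T"), m[1, j])[1]
    aln2 <- make_aln(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
    reg <- call_regions(window_profile(aln2))
    pairs <- enumerate_primer_pairs(aln2, reg, max_degeneracy = 1)
    expect_length(pairs, 0)
})

test_that("in-silico PCR recovers a planted amplicon exactly", {
    set.seed(36)
    fwd_site <- random_dna(20)
    rev_site <- random_dna(20)   # plus-strand segment the reverse primer covers
    fwd <- degenerate_primer("f", fwd_site, 1, 20, "forward")
    rev <- degenerate_primer("r", rc_plain(rev_site), 1, 20, "reverse")
    pair <- primer_pair(fwd, rev)
    tpl <- paste0(random_dna(1000), fwd_site, random_dna(760), rev_site,
                  random_dna(3000))
    amp <- insilico_pcr(tpl, pair)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$start, 1001L)
    expect_equal(amp$end, 1800L)
    expect_equal(amp$length, 800L)
    expect_equal(amp$strand, "+")
    expect_false(attr(amp, "nonspecific"))
})

test_that("a template without binding sites is PCR-negative", {
    set.seed(37)
    pair <- primer_pair(
        degenerate_primer("f", random_dna(20), 1, 20, "forward"),
        degenerate_primer("r", random_dna(20), 1, 20, "reverse"))
    amp <- insilico_pcr(random_dna(5000), pair)
    expect_equal(nrow(amp), 0L)
})

test_that("reverse-complementing the template mirrors amplicons", {
    set.seed(38)
    fwd_site <- random_dna(20); rev_site <- random_dna(20)
    pair <- primer_pair(
        degenerate_primer("f", fwd_site, 1, 20, "forward"),
        degenerate_primer("r", rc_plain(rev_site), 1, 20, "reverse"))
    tpl <- paste0(random_dna(500), fwd_site, random_dna(700), rev_site,
                  random_dna(500))
    a1 <- insilico_pcr(tpl, pair)
    a2 <- insilico_pcr(rc_plain(tpl), pair)
    expect_equal(nrow(a1), 1L)
    expect_equal(nrow(a2), 1L)
    expect_equal(a1$length, a2$length)
    expect_true(a1$strand != a2$strand)
    n <- nchar(tpl)
    expect_equal(a2$start, n - a1$end + 1L)
    expect_equal(a2$end, n - a1$start + 1L)
})

test_that("multiple products are flagged non-specific", {
    set.seed(39)
    fwd_site <- random_dna(20); rev_site <- random_dna(20)
    pair <- primer_pair(
        degenerate_primer("f", fwd_site, 1, 20, "forward"),
        degenerate_primer("r", rc_plain(rev_site), 1, 20, "reverse"))
    unit <- paste0(fwd_site, random_dna(700), rev_site)
    tpl <- paste0(random_dna(200), unit, random_dna(300), unit,
                  random_dna(200))
    amp <- insilico_pcr(tpl, pair)
    expect_gt(nrow(amp), 1L)
    expect_true(attr(amp, "nonspecific"))
})

test_that("degenerate primers match by IUPAC set membership", {
    # reverse primer is the IUPAC reverse complement of the plus-strand
    # site GGATCKGGYTTYACGATCAA
    pair <- primer_pair(
        degenerate_primer("f", "ARNGTSACSCCNAAGGGWCT", 1, 20, "forward"),
        degenerate_primer("r", "TTGATCGTRAARCCMGATCC", 1, 20, "reverse"))
    tpl <- paste0(strrep("T", 100), "AGCGTGACGCCTAAGGGACT",
                  strrep("C", 660), "GGATCTGGCTTTACGATCAA", strrep("T", 100))
    amp <- insilico_pcr(tpl, pair)
    expect_equal(nrow(amp), 1L)
    expect_equal(amp$length, 700L)
})

test_that("the published broad-range primer panel is internally consistent", {
    p <- actino_primer_set()
    # degeneracies from the IUPAC code sizes (e.g. rpoB-F: H*S*S*N = 48)
    expect_equal(vapply(p$fwd_seq, degeneracy, numeric(1),
                        USE.NAMES = FALSE), c(48, 72, 36))
    expect_equal(vapply(p$rev_seq, degeneracy, numeric(1),
                        USE.NAMES = FALSE), c(24, 64, 24))
    expect_true(all(nchar(c(p$fwd_seq, p$rev_seq)) %in% 17:21))
    # concatenated expected fragment sizes for the three-gene scheme
    expect_equal(sum(p$expected_bp), 2244L)
    expect_true(sum(p$expected_bp) >= 2220 && sum(p$expected_bp) <= 2274)
})
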