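test_that("pairwise identity counts columns like the brute force", {
    expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
    expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 87.5)
    # both-gap columns skipped; single-gap columns are mismatches
    expect_equal(pairwise_identity("AC-TA-", "ACGTA-"), 100 * 4 / 5)
    set.seed(71)
    for (i in 1:10) {
        a <- random_dna(120); b <- random_dna(120)
        bf <- 100 * mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
        expect_equal(pairwise_identity(a, b), bf)
    }
    expect_error(pairwise_identity("", "A"), "empty")
    expect_error(pairwise_identity("ACG", "AC"), "equal length")
})

test_that("unaligned identity routes through global alignment", {
    # one deletion: 99 identical columns over 100 alignment columns
    a <- strrep("ACGTG", 20)
    b <- paste0(substr(a, 1, 49), substr(a, 51, 100))
    expect_equal(pairwise_identity(a, b, aligned = FALSE), 99)
})

test_that("build_pairs crosses all taxon pairs against genome similarities", {
    set.seed(72)
    taxa <- paste0("t", 1:5)
    frags <- setNames(lapply(taxa, function(x) random_dna(200)), taxa)
    prs <- t(combn(taxa, 2))
    gs <- data.frame(taxon_a = prs[, 1], taxon_b = prs[, 2],
                     gcr = runif(nrow(prs), 80, 100))
    pairs <- build_pairs(frags, gs)
    expect_equal(nrow(pairs), 10L)   # C(5,2)
    expect_true(all(pairs$ss >= 0 & pairs$ss <= 100))
    # missing genome similarity is a hard error naming the pair
    expect_error(build_pairs(frags, gs[-3, ]), gs$taxon_b[3])
})

test_that("dedup collapses 100%-identical taxa when requested", {
    set.seed(73)
    s <- random_dna(150)
    frags <- list(t1 = s, t2 = s, t3 = random_dna(150))
    prs <- t(combn(names(frags), 2))
    gs <- data.frame(taxon_a = prs[, 1], taxon_b = prs[, 2], gcr = 90)
    expect_equal(nrow(build_pairs(frags, gs)), 3L)
    expect_equal(nrow(build_pairs(frags, gs, dedup_identical = TRUE)), 1L)
})

test_that("quadratic fit recovers noiseless coefficients exactly", {
    ss <- seq(60, 100, by = 2)
    gcr <- 0.02 * ss^2 - 2.8 * ss + 170
    m <- fit_quadratic(data.frame(ss = ss, gcr = gcr), "exact")
    expect_equal(m$a, 0.02, tolerance = 1e-9)
    expect_equal(m$b, -2.8, tolerance = 1e-9)
    expect_equal(m$c, 170, tolerance = 1e-9)
    expect_equal(m$r2, 1, tolerance = 1e-9)
    expect_error(fit_quadratic(data.frame(ss = rep(80, 10), gcr = 1:10)),
                 "degenerate")
})

test_that("noisy quadratic data recovers coefficients within 3 SE", {
    set.seed(74)
    ss <- runif(200, 60, 100)
    gcr <- 0.02 * ss^2 - 2.8 * ss + 170 + rnorm(200, sd = 1)
    m <- fit_quadratic(data.frame(ss = ss, gcr = gcr), "noisy")
    se <- summary(m$fit)$coefficients[, "Std. Error"]
    expect_lt(abs(m$a - 0.02), 3 * se[["I(ss^2)"]])
    expect_lt(abs(m$b - -2.8), 3 * se[["ss"]])
    expect_lt(abs(m$c - 170), 3 * se[["(Intercept)"]])
    expect_lt(m$r2, 1)
    # implementation r2 equals the independent 1 - SSres/SStot computation
    pred <- m$a * ss^2 + m$b * ss + m$c
    r2_bf <- 1 - sum((gcr - pred)^2) / sum((gcr - mean(gcr))^2)
    expect_equal(m$r2, r2_bf, tolerance = 1e-9)
})

test_that("shifting gcr by a constant shifts only the intercept", {
    set.seed(75)
    ss <- runif(50, 60, 100)
    gcr <- 0.015 * ss^2 - 2 * ss + 150 + rnorm(50, sd = 0.5)
    m1 <- fit_quadratic(data.frame(ss = ss, gcr = gcr))
    m2 <- fit_quadratic(data.frame(ss = ss, gcr = gcr + 5))
    expect_equal(m1$a, m2$a, tolerance = 1e-9)
    expect_equal(m1$b, m2$b, tolerance = 1e-9)
    expect_equal(m2$c - m1$c, 5, tolerance = 1e-9)
})

test_that("prediction evaluates the quadratic with clamping and flags", {
    combined <- quadratic_gcr_model(0.0212, -2.873, 172.14,
                                    "ychF+rpoB+secY", ss_range = c(60, 100))
    expect_equal(as.numeric(predict_gcr(combined, 100)), 96.84,
                 tolerance = 1e-9)
    ident <- quadratic_gcr_model(0, 1, 0, "identity")
    expect_equal(as.numeric(predict_gcr(ident, 75)), 75)
    big <- quadratic_gcr_model(0, 0, 150, "overflow")
    p <- predict_gcr(big, 50)
    expect_equal(as.numeric(p), 100)
    expect_true(attr(p, "clamped"))
    expect_true(attr(predict_gcr(combined, 40), "extrapolated"))
    # noiseless round trip through fit + predict
    ss <- seq(50, 100, by = 5)
    gcr <- 0.01 * ss^2 - ss + 80
    m <- fit_quadratic(data.frame(ss = ss, gcr = gcr))
    expect_equal(as.numeric(predict_gcr(m, ss)), gcr, tolerance = 1e-6)
})

test_that("gene ranking selects models strictly above the R2 threshold", {
    mk <- function(g, r2) quadratic_gcr_model(0, 1, 0, g, r2 = r2,
                                              n_pairs = 10)
    rk <- rank_genes(list(mk("g1", 0.91), mk("g2", 0.87), mk("g3", 0.86),
                          mk("g4", 0.79)), r2_threshold = 0.85)
    expect_equal(rk$selected, c("g1", "g2", "g3"))
    expect_equal(rk$ranking$gene, c("g1", "g2", "g3", "g4"))
    rk2 <- rank_genes(list(mk("g1", 0.5)), r2_threshold = 0.85)
    expect_length(rk2$selected, 0)
})

test_that("tree-concordant genes outrank a tree-discordant gene", {
    w <- small_world()
    gs <- small_world_gcr()
    frag_seqs <- function(g) {
        e <- w$catalogue[[g]]$seqs
        lapply(e, substr, start = 51, stop = 800)  # hypervariable core
    }
    fits <- lapply(c("marA", "errH"), function(g)
        fit_quadratic(build_pairs(frag_seqs(g), gs), g))
    expect_gt(fits[[1]]$r2, 0.85)
    expect_lt(fits[[2]]$r2, fits[[1]]$r2)
})

test_that("intraspecies summaries stay within species boundaries", {
    set.seed(76)
    s <- random_dna(300)
    mut1 <- function(s, k) {
        ch <- strsplit(s, "")[[1]]
        at <- sample(length(ch), k)
        ch[at] <- vapply(ch[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        paste(ch, collapse = "")
    }
    labeled <- list(
        cloneSp = list(a = s, b = s, c = s),
        diverseSp = list(a = s, b = mut1(s, 3), c = mut1(s, 6)),
        loner = list(a = s))
    expect_message(out <- intraspecies_summary(labeled), "loner")
    expect_equal(out$species, c("cloneSp", "diverseSp"))
    expect_equal(out$min_similarity[1], 100)
    expect_equal(out$max_similarity[1], 100)
    expect_lt(out$min_similarity[2], 100)
    expect_gte(out$min_similarity[2], 97)
})
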