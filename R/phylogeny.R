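PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P the transition and Q the transversion proportion over comparable
#' columns, `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Columns with a
#' gap (or `N`, treated as a gap) in either sequence are skipped (pairwise
#' deletion). Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise an
#' error.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @return Substitutions per site (>= 0).
#' @export
k2p_distance <- function(seq_a, seq_b) {
    a <- strsplit(toupper(as_seqstring(seq_a)), "", fixed = TRUE)[[1]]
    b <- strsplit(toupper(as_seqstring(seq_b)), "", fixed = TRUE)[[1]]
    if (length(a) != length(b)) stop("sequences must have equal length")
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    n <- sum(ok)
    if (n == 0L) stop("no comparable (both non-gap) columns")
    a <- a[ok]; b <- b[ok]
    diff <- a != b
    ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
    P <- sum(ts) / n
    Q <- sum(diff & !ts) / n
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
        stop("saturated pair: K2P distance undefined (P = ", round(P, 3),
             ", Q = ", round(Q, 3), ")")
    -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance matrix of an alignment
#'
#' @param aln A `multi_alignment` (or character matrix, rows = taxa).
#' @param on_saturation `"error"` or `"na"` for saturated pairs.
#' @return Symmetric `dist`-compatible matrix with zero diagonal.
#' @export
k2p_matrix <- function(aln, on_saturation = c("error", "na")) {
    on_saturation <- match.arg(on_saturation)
    m <- if (is.matrix(aln)) aln else aln_matrix(aln)
    nt <- nrow(m)
    cmp <- m %in% c("A", "C", "G", "T")
    dim(cmp) <- dim(m)
    d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(nt - 1L)) {
        for (j in (i + 1L):nt) {
            ok <- cmp[i, ] & cmp[j, ]
            n <- sum(ok)
            if (n == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
            a <- m[i, ok]; b <- m[j, ok]
            diff <- a != b
            ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                          (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
            P <- sum(ts) / n; Q <- sum(diff & !ts) / n
            w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
            if (w1 <= 0 || w2 <= 0) {
                if (on_saturation == "error")
                    stop("saturated pair: ", rownames(m)[i], " vs ",
                         rownames(m)[j])
                d[i, j] <- d[j, i] <- NA_real_
            } else {
                d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
            }
        }
    }
    d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); any negative branch length
#' is clamped to zero with the deficit transferred to the sister branch, so
#' path lengths through the parent node are preserved where possible.
#'
#' @param dm Symmetric numeric matrix with taxon dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
    if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")
    if (any(is.na(dm))) stop("distance matrix contains NA")
    tr <- ape::nj(as.dist(dm))
    neg <- which(tr$edge.length < 0)
    for (e in neg) {
        parent <- tr$edge[e, 1]
        sisters <- setdiff(which(tr$edge[, 1] == parent), e)
        if (length(sisters) > 0)
            tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] +
                tr$edge.length[e]
        tr$edge.length[e] <- 0
    }
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

# canonical bipartition keys for the internal edges of an unrooted tree:
# each internal edge splits the taxa; the side not containing the
# alphabetically first taxon, sorted and joined, is the key
tree_bipartitions <- function(tree) {
    ntip <- length(tree$tip.label)
    anchor <- sort(tree$tip.label)[1]
    keys <- character(0)
    internal <- which(tree$edge[, 2] > ntip)
    if (length(internal) == 0L) return(keys)
    for (e in internal) {
        node <- tree$edge[e, 2]
        tips <- tree$tip.label[phangorn_descendants(tree, node, ntip)]
        if (anchor %in% tips)
            tips <- setdiff(tree$tip.label, tips)
        if (length(tips) < 2L || length(tips) > ntip - 2L) next
        keys <- c(keys, paste(sort(tips), collapse = "|"))
    }
    keys
}

# tip indices descending from an internal node (iterative, no deps)
phangorn_descendants <- function(tree, node, ntip) {
    out <- integer(0)
    stack <- node
    while (length(stack) > 0L) {
        nd <- stack[[1]]; stack <- stack[-1]
        kids <- tree$edge[tree$edge[, 1] == nd, 2]
        out <- c(out, kids[kids <= ntip])
        stack <- c(stack, kids[kids > ntip])
    }
    out
}

#' Bootstrap node support for the neighbor-joining tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and scores each internal edge of the full-data tree by
#' the percentage of replicates containing the same taxon bipartition.
#' Replicates whose distance matrix saturates are skipped and counted; more
#' than 10 percent unusable replicates is an error.
#'
#' @param aln A `multi_alignment`.
#' @param n_reps Number of bootstrap replicates (1000 by convention).
#' @param seed Mandatory RNG seed.
#' @return The full-data NJ tree (`phylo`) with `node.label` carrying
#'   percent support on internal nodes and attributes `supports` (named
#'   numeric, bipartition key -> percent) and `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed) {
    if (missing(seed)) stop("seed is required")
    m <- aln_matrix(aln)
    full <- nj_tree(k2p_matrix(m))
    keys <- tree_bipartitions(full)
    counts <- setNames(numeric(length(keys)), keys)
    skipped <- 0L
    set.seed(seed)
    ncol_m <- ncol(m)
    for (r in seq_len(n_reps)) {
        cols <- sample.int(ncol_m, ncol_m, replace = TRUE)
        dm <- k2p_matrix(m[, cols, drop = FALSE], on_saturation = "na")
        if (any(is.na(dm))) { skipped <- skipped + 1L; next }
        bt <- nj_tree(dm)
        bk <- tree_bipartitions(bt)
        hit <- keys %in% bk
        counts[hit] <- counts[hit] + 1
    }
    if (skipped > 0.10 * n_reps)
        stop(skipped, " of ", n_reps, " bootstrap replicates unusable")
    used <- n_reps - skipped
    supports <- 100 * counts / max(1L, used)
    # attach supports as node labels of the full tree
    ntip <- length(full$tip.label)
    nnode <- full$Nnode
    labels <- rep("", nnode)
    anchor <- sort(full$tip.label)[1]
    for (e in which(full$edge[, 2] > ntip)) {
        node <- full$edge[e, 2]
        tips <- full$tip.label[phangorn_descendants(full, node, ntip)]
        if (anchor %in% tips) tips <- setdiff(full$tip.label, tips)
        key <- paste(sort(tips), collapse = "|")
        if (key %in% names(supports))
            labels[node - ntip] <- format(round(supports[[key]], 1))
    }
    full$node.label <- labels
    attr(full, "supports") <- supports
    attr(full, "n_skipped") <- skipped
    full
}

#' Summarise bootstrap support above a threshold
#'
#' Counts internal edges with support strictly greater than `threshold`
#' percent, the paper-style "percentage of well-supported nodes" summary
#' used to compare marker sets.
#'
#' @param tree Tree from [bootstrap_support()], or a numeric vector of
#'   supports.
#' @param threshold Percent (strict inequality).
#' @return List of class `support_summary`: `n_internal_nodes`,
#'   `n_above_threshold`, `percent_above`, `threshold`.
#' @export
support_summary <- function(tree, threshold = 65) {
    supports <- if (is.numeric(tree)) tree else attr(tree, "supports")
    if (is.null(supports) || length(supports) == 0L)
        stop("tree carries no bootstrap supports")
    n <- length(supports)
    above <- sum(supports > threshold)
    structure(list(n_internal_nodes = n, n_above_threshold = above,
                   percent_above = 100 * above / n, threshold = threshold),
              class = "support_summary")
}

#' @export
print.support_summary <- function(x, ...) {
    cat("<support_summary> ", x$n_above_threshold, "/", x$n_internal_nodes,
        " nodes (", round(x$percent_above, 1), "%) above ", x$threshold,
        "% support\n", sep = "")
    invisible(x)
}

#' Chi-square comparison of node-support summaries of two trees
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 table of internal nodes above/below the support threshold in each
#' tree; tests whether one marker set yields significantly more
#' well-supported nodes than the other.
#'
#' @param summary_a,summary_b `support_summary` objects.
#' @param correct Apply Yates continuity correction.
#' @return List with `chi2`, `p_value`, `table`.
#' @export
compare_support <- function(summary_a, summary_b, correct = FALSE) {
    tab <- rbind(a = c(above = summary_a$n_above_threshold,
                       below = summary_a$n_internal_nodes -
                           summary_a$n_above_threshold),
                 b = c(above = summary_b$n_above_threshold,
                       below = summary_b$n_internal_nodes -
                           summary_b$n_above_threshold))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero marginal in the support table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value),
         table = tab)
}

#' Write a tree with supports as Newick
#'
#' @param tree `phylo` tree (supports in `node.label` if present).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}
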