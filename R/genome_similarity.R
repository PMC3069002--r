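#' Find maximal unique matches (MUMs) between two sequences
#'
#' A MUM is an exact match that cannot be extended in either direction and
#' occurs exactly once in each sequence. Both the forward query strand and
#' its reverse complement are searched; uniqueness is assessed within the
#' orientation being scanned. Implemented with a suffix array plus LCP
#' table over the concatenated sequences.
#'
#' @param ref,query [seq_record()] or plain strings, ungapped.
#' @param min_len Minimum match length (anchor resolution).
#' @return data.frame with `ref_start`, `query_start`, `length`, `strand`.
#'   For `-` strand rows, `query_start` is 1-based on the
#'   reverse-complemented query (the coordinate frame in which the match is
#'   colinear with the reference).
#' @export
find_mums <- function(ref, query, min_len = 12L) {
    rs <- as_seqstring(ref); qs <- as_seqstring(query)
    if (nchar(rs) < min_len || nchar(qs) < min_len)
        stop("sequences must be at least min_len (", min_len, ") long")
    fwd <- .mums_one_strand(rs, qs, min_len)
    rev <- .mums_one_strand(rs, revcomp(qs), min_len)
    out <- rbind(
        if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
        if (nrow(rev)) cbind(rev, strand = "-") else NULL)
    if (is.null(out))
        out <- data.frame(ref_start = integer(0), query_start = integer(0),
                          length = integer(0), strand = character(0))
    out[order(out$strand, out$ref_start), , drop = FALSE]
}

as_seqstring <- function(x) {
    if (inherits(x, "seq_record")) return(x$seq)
    toupper(x)
}

#' Chain MUM anchors into colinear clusters
#'
#' Greedy colinear chaining in reference order: a match joins the current
#' cluster when both the reference and query gaps to the previous anchor
#' are at most `max_gap` and the diagonal shift is at most
#' `diag_factor` times the gap length. Clusters carrying fewer than
#' `min_cluster` matched bases are discarded as noise.
#'
#' @param matches data.frame as from [find_mums()], one strand only.
#' @param max_gap Largest anchor-to-anchor gap, bp.
#' @param diag_factor Allowed diagonal drift per gap base.
#' @param min_cluster Minimum total matched bases per retained cluster.
#' @return List of data.frames (the clustered anchors, reference-ordered).
#' @export
cluster_matches <- function(matches, max_gap = 250, diag_factor = 0.15,
                            min_cluster = 40) {
    if (nrow(matches) == 0L) return(list())
    if (length(unique(matches$strand)) > 1L)
        stop("cluster_matches expects matches from a single strand")
    m <- matches[order(matches$ref_start, matches$query_start), , drop = FALSE]
    clusters <- list()
    cur <- m[1, , drop = FALSE]
    for (i in seq_len(nrow(m))[-1]) {
        last <- cur[nrow(cur), ]
        gap_r <- m$ref_start[i] - (last$ref_start + last$length)
        gap_q <- m$query_start[i] - (last$query_start + last$length)
        diag_shift <- abs((m$ref_start[i] - m$query_start[i]) -
                          (last$ref_start - last$query_start))
        gap <- max(gap_r, gap_q)
        ok <- m$ref_start[i] > last$ref_start &&
            m$query_start[i] > last$query_start &&
            gap_r <= max_gap && gap_q <= max_gap &&
            diag_shift <= diag_factor * max(gap, 1)
        if (ok) {
            cur <- rbind(cur, m[i, ])
        } else {
            clusters[[length(clusters) + 1L]] <- cur
            cur <- m[i, , drop = FALSE]
        }
    }
    clusters[[length(clusters) + 1L]] <- cur
    clusters[vapply(clusters, function(cl) sum(cl$length), numeric(1)) >=
             min_cluster]
}

# ungapped x-drop extension from (rpos, qpos) moving by `dir` (+1/-1);
# returns c(n_bases, n_matched) of the best-scoring extension prefix,
# looking at most `breaklen` bases ahead.
xdrop_extend <- function(refc, qryc, rpos, qpos, dir, breaklen,
                         match = 1, mismatch = -3) {
    nmax <- if (dir > 0)
        min(length(refc) - rpos, length(qryc) - qpos, breaklen)
    else
        min(rpos - 1L, qpos - 1L, breaklen)
    if (nmax <= 0L) return(c(0L, 0L))
    ri <- rpos + dir * seq_len(nmax)
    qi <- qpos + dir * seq_len(nmax)
    eq <- refc[ri] == qryc[qi]
    sc <- cumsum(ifelse(eq, match, mismatch))
    best <- which.max(sc)
    if (sc[best] <= 0) return(c(0L, 0L))
    c(best, sum(eq[seq_len(best)]))
}

#' Close inter-anchor gaps of a cluster into homologous regions
#'
#' Aligns the sequence between consecutive anchors by global alignment and
#' fuses anchors plus gap alignments into regions carrying percent
#' identity. A gap longer than `2 * breaklen` on either sequence splits the
#' cluster into separate regions. Region ends are extended outward by
#' ungapped alignment that abandons after `breaklen` bases without a new
#' score maximum.
#'
#' @param ref Reference sequence ([seq_record()] or string).
#' @param query Query sequence; pass the reverse complement for a `-`
#'   strand cluster.
#' @param cluster One cluster from [cluster_matches()].
#' @param breaklen Extension/split budget in bp.
#' @param match,mismatch,gap_open,gap_ext Alignment scores for gap closing.
#' @return data.frame with `ref_start`, `ref_end`, `query_start`,
#'   `query_end` (oriented frame), `length` (alignment columns),
#'   `matched`, `identity` (percent).
#' @export
close_gaps <- function(ref, query, cluster, breaklen = 500,
                       match = 1, mismatch = -3, gap_open = -5,
                       gap_ext = -1) {
    rs <- as_seqstring(ref); qs <- as_seqstring(query)
    refc <- strsplit(rs, "", fixed = TRUE)[[1]]
    qryc <- strsplit(qs, "", fixed = TRUE)[[1]]
    cl <- cluster[order(cluster$ref_start), , drop = FALSE]
    regions <- list()
    # accumulators for the open region
    r0 <- cl$ref_start[1]; q0 <- cl$query_start[1]
    re <- r0 + cl$length[1] - 1L; qe <- q0 + cl$length[1] - 1L
    matched <- cl$length[1]; columns <- cl$length[1]
    flush <- function() {
        regions[[length(regions) + 1L]] <<- data.frame(
            ref_start = r0, ref_end = re, query_start = q0, query_end = qe,
            length = columns, matched = matched,
            identity = 100 * matched / columns)
    }
    for (i in seq_len(nrow(cl))[-1]) {
        a_r <- cl$ref_start[i]; a_q <- cl$query_start[i]; a_len <- cl$length[i]
        # trim anchor if it overlaps the open region end
        ov <- max(0L, re - a_r + 1L, qe - a_q + 1L)
        a_r <- a_r + ov; a_q <- a_q + ov; a_len <- a_len - ov
        if (a_len <= 0L) next
        gr <- a_r - re - 1L; gq <- a_q - qe - 1L
        if (max(gr, gq) > 2L * breaklen) {
            flush()
            r0 <- a_r; q0 <- a_q
            re <- a_r + a_len - 1L; qe <- a_q + a_len - 1L
            matched <- a_len; columns <- a_len
            next
        }
        if (gr > 0L || gq > 0L) {
            if (gr == 0L || gq == 0L) {
                # pure insertion: all gap columns, no matches
                matched <- matched + 0L
                columns <- columns + max(gr, gq)
            } else {
                al <- .nw_align(substr(rs, re + 1L, a_r - 1L),
                                substr(qs, qe + 1L, a_q - 1L),
                                match, mismatch, gap_open, gap_ext)
                matched <- matched + al$matched
                columns <- columns + al$columns
            }
        }
        matched <- matched + a_len
        columns <- columns + a_len
        re <- a_r + a_len - 1L; qe <- a_q + a_len - 1L
    }
    flush()
    out <- do.call(rbind, regions)
    # terminal extension of the first and last region ends
    ext <- xdrop_extend(refc, qryc, out$ref_start[1], out$query_start[1],
                        -1L, breaklen, match, mismatch)
    out$ref_start[1] <- out$ref_start[1] - ext[1]
    out$query_start[1] <- out$query_start[1] - ext[1]
    out$length[1] <- out$length[1] + ext[1]
    out$matched[1] <- out$matched[1] + ext[2]
    n <- nrow(out)
    ext <- xdrop_extend(refc, qryc, out$ref_end[n], out$query_end[n],
                        1L, breaklen, match, mismatch)
    out$ref_end[n] <- out$ref_end[n] + ext[1]
    out$query_end[n] <- out$query_end[n] + ext[1]
    out$length[n] <- out$length[n] + ext[1]
    out$matched[n] <- out$matched[n] + ext[2]
    out$identity <- 100 * out$matched / out$length
    out
}

#' Split overlapping homologous regions at the midpoint of the shared span
#'
#' When two regions share reference bases, the common segment is divided
#' equally between them; identities are recomputed proportionally on the
#' trimmed spans. A region fully contained in (or identical to) an earlier
#' one is dropped.
#'
#' @param regions data.frame of regions sorted (or sortable) by
#'   `ref_start`, with `ref_start`, `ref_end`, `length`, `matched`,
#'   `identity` columns.
#' @return The non-overlapping region set.
#' @export
resolve_overlaps <- function(regions) {
    if (nrow(regions) <= 1L) return(regions)
    rg <- regions[order(regions$ref_start, regions$ref_end), , drop = FALSE]
    scale_region <- function(r, new_start, new_end) {
        old_span <- r$ref_end - r$ref_start + 1
        new_span <- new_end - new_start + 1
        f <- new_span / old_span
        r$ref_start <- new_start; r$ref_end <- new_end
        r$length <- max(1, round(r$length * f))
        r$matched <- r$matched * f
        r
    }
    out <- rg[1, , drop = FALSE]
    for (i in seq_len(nrow(rg))[-1]) {
        b <- rg[i, , drop = FALSE]
        a <- out[nrow(out), , drop = FALSE]
        if (b$ref_start > a$ref_end) {           # disjoint
            out <- rbind(out, b)
        } else if (b$ref_end <= a$ref_end) {     # contained / duplicate: drop
            next
        } else {                                 # partial overlap: split
            mid <- floor((b$ref_start + a$ref_end) / 2)
            out[nrow(out), ] <- scale_region(a, a$ref_start, mid)
            out <- rbind(out, scale_region(b, mid + 1, b$ref_end))
        }
    }
    out$identity <- 100 * out$matched / out$length
    rownames(out) <- NULL
    out
}

# full anchor->cluster->gap-closing pass for one (ref, query) direction,
# with query coordinates reported on the forward query strand
regions_one_direction <- function(rs, qs, min_match, max_gap, diag_factor,
                                  min_cluster, breaklen) {
    mums <- find_mums(rs, qs, min_match)
    nq <- nchar(qs)
    out <- list()
    for (strand in c("+", "-")) {
        mm <- mums[mums$strand == strand, , drop = FALSE]
        if (nrow(mm) == 0L) next
        qseq <- if (strand == "+") qs else revcomp(qs)
        for (cl in cluster_matches(mm, max_gap, diag_factor, min_cluster)) {
            rg <- close_gaps(rs, qseq, cl, breaklen)
            if (strand == "-") {
                q1 <- nq - rg$query_end + 1L
                q2 <- nq - rg$query_start + 1L
                rg$query_start <- q1; rg$query_end <- q2
            }
            rg$strand <- strand
            out[[length(out) + 1L]] <- rg
        }
    }
    if (length(out) == 0L) return(NULL)
    do.call(rbind, out)
}

#' Whole-genome conserved-region similarity (GCR)
#'
#' Anchors the two genomes with MUMs, chains anchors into colinear
#' clusters, closes inter-anchor gaps by alignment, repeats the analysis
#' with reference and query swapped so no alignable region is missed,
#' resolves overlapping regions by splitting shared reference segments at
#' their midpoint, and reports the mean identity of the homologous regions
#' weighted by each region's length in nucleotides.
#'
#' @param ref,query Genomes ([seq_record()] or strings).
#' @param min_match MUM anchor length (12).
#' @param max_gap,diag_factor,min_cluster Anchor chaining parameters
#'   (250, 0.15, 40).
#' @param breaklen Gap-closing/extension budget (500).
#' @return List of class `conserved_similarity`: `regions` (non-overlapping
#'   on the reference), `gcr_similarity` (percent, `NA` when no region was
#'   found), `covered_fraction_ref`, `covered_fraction_query`, `n_regions`.
#' @export
conserved_similarity <- function(ref, query, min_match = 12L, max_gap = 250,
                                 diag_factor = 0.15, min_cluster = 40,
                                 breaklen = 500) {
    rs <- as_seqstring(ref); qs <- as_seqstring(query)
    fwd <- regions_one_direction(rs, qs, min_match, max_gap, diag_factor,
                                 min_cluster, breaklen)
    swp <- regions_one_direction(qs, rs, min_match, max_gap, diag_factor,
                                 min_cluster, breaklen)
    if (!is.null(swp)) {      # swap intervals back into the (ref, query) frame
        tmp_s <- swp$ref_start; tmp_e <- swp$ref_end
        swp$ref_start <- swp$query_start; swp$ref_end <- swp$query_end
        swp$query_start <- tmp_s; swp$query_end <- tmp_e
    }
    regions <- rbind(fwd, swp)
    if (is.null(regions) || nrow(regions) == 0L) {
        return(structure(list(regions = NULL, gcr_similarity = NA_real_,
                              covered_fraction_ref = 0,
                              covered_fraction_query = 0, n_regions = 0L),
                         class = "conserved_similarity"))
    }
    regions <- resolve_overlaps(regions)
    gcr <- sum(regions$identity * regions$length) / sum(regions$length)
    cov_ref <- sum(regions$ref_end - regions$ref_start + 1) / nchar(rs)
    qiv <- regions[order(regions$query_start), c("query_start", "query_end")]
    covered_q <- 0; cur_end <- 0
    for (i in seq_len(nrow(qiv))) {
        s <- max(qiv$query_start[i], cur_end + 1)
        if (qiv$query_end[i] >= s) {
            covered_q <- covered_q + qiv$query_end[i] - s + 1
            cur_end <- max(cur_end, qiv$query_end[i])
        }
    }
    structure(list(regions = regions, gcr_similarity = gcr,
                   covered_fraction_ref = min(1, cov_ref),
                   covered_fraction_query = min(1, covered_q / nchar(qs)),
                   n_regions = nrow(regions)),
              class = "conserved_similarity")
}

#' @export
print.conserved_similarity <- function(x, ...) {
    cat("<conserved_similarity> ", x$n_regions, " regions, GCR = ",
        round(x$gcr_similarity, 2), "%, ref coverage ",
        round(100 * x$covered_fraction_ref, 1), "%\n", sep = "")
    invisible(x)
}
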