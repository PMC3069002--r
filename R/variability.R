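#' Per-column variability of an alignment column
#'
#' Variability is `100 * (1 - n_modal / n_nongap)` where `n_modal` counts the
#' most frequent non-gap residue. An invariant column scores 0; a column
#' with no single dominant residue approaches 100. A column consisting only
#' of gaps scores 100 (it carries no conserved primer-binding information).
#'
#' @param column Character vector of residues, possibly including `-`.
#' @return Percent in \[0, 100\].
#' @export
column_variability <- function(column) {
    if (length(column) < 2L) stop("a column needs at least 2 residues")
    res <- column[column != "-"]
    if (length(res) == 0L) return(100)
    100 * (1 - max(table(res)) / length(res))
}

#' Windowed mean-variability profile of an alignment
#'
#' Tiles the alignment with windows of `window_size` columns advancing by
#' `step` (successive non-overlapping 50-column windows by default) and
#' reports each window's arithmetic mean of per-column variabilities. A
#' trailing window shorter than `window_size` is reported but flagged
#' `partial` and is excluded from region calling.
#'
#' @param aln A `multi_alignment`.
#' @param window_size,step Window width and advance, in columns.
#' @return data.frame of class `variability_profile` with columns
#'   `window_start`, `window_end` (1-based inclusive), `mean_variability`
#'   (percent), `partial` (logical); attributes `window_size`, `step`.
#' @export
window_profile <- function(aln, window_size = 50L, step = 50L) {
    if (window_size < 1L) stop("window_size must be >= 1")
    if (step < 1L) stop("step must be >= 1")
    if (window_size > aln$length)
        stop("window_size (", window_size, ") exceeds alignment length (",
             aln$length, ")")
    m <- aln_matrix(aln)
    colvar <- apply(m, 2L, column_variability)
    starts <- seq(1L, aln$length, by = step)
    ends <- pmin(starts + window_size - 1L, aln$length)
    keep <- starts <= aln$length
    starts <- starts[keep]; ends <- ends[keep]
    # drop fully duplicated trailing windows that would start past the end
    vals <- vapply(seq_along(starts), function(i)
        mean(colvar[starts[i]:ends[i]]), numeric(1))
    out <- data.frame(window_start = starts, window_end = ends,
                      mean_variability = vals,
                      partial = (ends - starts + 1L) < window_size)
    attr(out, "window_size") <- window_size
    attr(out, "step") <- step
    class(out) <- c("variability_profile", "data.frame")
    out
}

#' Call conserved and hypervariable regions from a variability profile
#'
#' Maximal runs of consecutive full windows with mean variability strictly
#' below `conserved_threshold` become conserved regions; the remaining runs
#' are hypervariable. Broad-range primers are designed inside conserved
#' regions (the default threshold of 15 percent reflects the empirical
#' ceiling for reliable degenerate primer binding sites); hypervariable
#' regions are the identification targets in between.
#'
#' @param profile A `variability_profile`.
#' @param conserved_threshold Percent; windows strictly below it are
#'   conserved.
#' @param min_conserved_windows Conserved runs shorter than this many
#'   windows are merged into the surrounding hypervariable region.
#' @return data.frame with columns `start`, `end` (1-based alignment
#'   columns), `kind` (`conserved`/`hypervariable`), `mean_variability`.
#' @export
call_regions <- function(profile, conserved_threshold = 15,
                         min_conserved_windows = 1L) {
    full <- profile[!profile$partial, , drop = FALSE]
    if (nrow(full) == 0L) stop("profile has no full windows")
    cons <- full$mean_variability < conserved_threshold
    if (min_conserved_windows > 1L) {
        r <- rle(cons)
        r$values[r$values & r$lengths < min_conserved_windows] <- FALSE
        cons <- inverse.rle(r)
    }
    r <- rle(cons)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    data.frame(
        start = full$window_start[idx_start],
        end = full$window_end[idx_end],
        kind = ifelse(r$values, "conserved", "hypervariable"),
        mean_variability = vapply(seq_along(r$values), function(i)
            mean(full$mean_variability[idx_start[i]:idx_end[i]]), numeric(1)),
        stringsAsFactors = FALSE)
}

#' Write a variability profile with region calls as TSV
#'
#' @param profile A `variability_profile`.
#' @param regions Output of [call_regions()] on the same profile.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, regions, path) {
    kind <- rep(NA_character_, nrow(profile))
    for (i in seq_len(nrow(regions)))
        kind[profile$window_start >= regions$start[i] &
             profile$window_end <= regions$end[i]] <- regions$kind[i]
    out <- cbind(profile, region_kind = kind)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
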