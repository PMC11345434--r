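#' Define a directional contrast between two region sets
#'
#' A preplanned forward-vs-backward comparison: the forward direction pools
#' the coupling from every region in `source` to every region in `target`,
#' the backward direction the reverse links.
#'
#' @param name label for the contrast.
#' @param source character vector of sender region names (non-empty).
#' @param target character vector of receiver region names (non-empty,
#'   disjoint from `source`).
#' @return An object of class `directional_contrast`.
#' @export
directional_contrast <- function(name, source, target) {
  if (length(source) < 1 || length(target) < 1)
    stop("`source` and `target` must be non-empty", call. = FALSE)
  if (length(intersect(source, target)) > 0)
    stop("`source` and `target` must be disjoint (shared: ",
         paste(intersect(source, target), collapse = ", "), ")",
         call. = FALSE)
  structure(list(name = name, source = as.character(source),
                 target = as.character(target)),
            class = "directional_contrast")
}

#' @export
print.directional_contrast <- function(x, ...) {
  cat("<directional_contrast> ", x$name, ": {",
      paste(x$source, collapse = ", "), "} -> {",
      paste(x$target, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' The six preplanned directional contrasts
#'
#' The forward-vs-backward comparisons tested across participants in the
#' ventromedial (scene) and ventrolateral (face) visual streams: V3/V4 to the
#' prostriate retrosplenial scene region; V3/V4 to the ventromedial visual
#' regions; V3 to the medial parahippocampal regions; the parahippocampal
#' scene regions to the hippocampus; and FFC/PIT/V8 to inferior temporal TE2p
#' and to anterior temporal TE2a.
#'
#' @return A list of six [directional_contrast()] objects.
#' @export
preplanned_contrasts <- function() {
  list(
    directional_contrast("V3-V4 -> ProS", c("V3", "V4"), "ProS"),
    directional_contrast("V3-V4 -> VMV/VVC", c("V3", "V4"),
                         c("VMV1", "VMV2", "VMV3", "VVC")),
    directional_contrast("V3 -> PHA1-3", "V3", c("PHA1", "PHA2", "PHA3")),
    directional_contrast("PHA1-3 -> Hipp", c("PHA1", "PHA2", "PHA3"), "Hipp"),
    directional_contrast("FFC/PIT/V8 -> TE2p", c("FFC", "PIT", "V8"), "TE2p"),
    directional_contrast("FFC/PIT/V8 -> TE2a", c("FFC", "PIT", "V8"), "TE2a")
  )
}

# internal: resolve contrast labels to matrix indices. Plain labels are used
# directly; if absent and the matrix is hemisphere-labelled ("name.L"), the
# per-hemisphere columns are returned (list of index vectors, one per block).
resolve_labels <- function(labels, mat_labels) {
  if (all(labels %in% mat_labels))
    return(list(match(labels, mat_labels)))
  blocks <- lapply(c("L", "R"), function(h) {
    lab_h <- paste(labels, h, sep = ".")
    if (all(lab_h %in% mat_labels)) match(lab_h, mat_labels) else NULL
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0) {
    bad <- labels[!(labels %in% mat_labels)][1]
    stop("region label '", bad, "' not resolvable in the matrix", call. = FALSE)
  }
  blocks
}

#' Pooled directional coupling for a contrast
#'
#' `forward` is the unweighted mean of `ec[target, source]` over all ordered
#' (source, target) pairs — the input each target receives from each source —
#' and `backward` the mean of `ec[source, target]`. With hemisphere-labelled
#' matrices (`name.L` / `name.R`) the within-hemisphere pools are averaged
#' across hemispheres.
#'
#' @param ec coupling matrix with region labels as dimnames.
#' @param contrast a [directional_contrast()].
#' @return Named numeric vector `c(forward, backward)`.
#' @export
pooled_directional_ec <- function(ec, contrast) {
  labs <- rownames(ec)
  if (is.null(labs)) stop("`ec` must carry region labels", call. = FALSE)
  src <- resolve_labels(contrast$source, labs)
  tgt <- resolve_labels(contrast$target, labs)
  if (length(src) != length(tgt))
    stop("source and target resolve to different hemisphere blocks",
         call. = FALSE)
  fwd <- mean(vapply(seq_along(src),
                     function(h) mean(ec[tgt[[h]], src[[h]]]), numeric(1)))
  bwd <- mean(vapply(seq_along(src),
                     function(h) mean(ec[src[[h]], tgt[[h]]]), numeric(1)))
  c(forward = fwd, backward = bwd)
}

#' Paired t-test on forward vs backward coupling across participants
#'
#' Standard two-tailed paired t-test on `d = forward - backward` with
#' `df = n - 1` (e.g. df = 20 for 21 participants). P values are reported
#' uncorrected — the intended use is a small set of preplanned contrasts.
#'
#' @param forward,backward numeric vectors of per-participant pooled coupling
#'   (equal length `n >= 2`).
#' @param name optional contrast label carried into the result.
#' @return An object of class `contrast_result`: list with `t`, `p`, `df`,
#'   `mean_difference`, `per_participant_forward`, `per_participant_backward`,
#'   `name`, `corrected = FALSE`.
#' @export
paired_directionality_test <- function(forward, backward, name = NULL) {
  if (length(forward) != length(backward))
    stop("`forward` and `backward` must have equal length", call. = FALSE)
  n <- length(forward)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  d <- forward - backward
  if (var(d) == 0)
    stop("degenerate contrast: zero variance in the paired differences",
         call. = FALSE)
  tt <- t.test(forward, backward, paired = TRUE, alternative = "two.sided")
  structure(
    list(name = name, t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean_difference = mean(d),
         per_participant_forward = forward,
         per_participant_backward = backward, corrected = FALSE),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result>", if (!is.null(x$name)) x$name, "\n  t = ",
      signif(x$t, 4), ", p = ", signif(x$p, 4), " (two-tailed, uncorrected), ",
      "df = ", x$df, ", mean diff = ", signif(x$mean_difference, 4), "\n",
      sep = "")
  invisible(x)
}

#' @describeIn paired_directionality_test One-row tibble with `name`, `t`,
#'   `p`, `df`, `mean_difference`, `n`, `corrected`.
#' @param x a `contrast_result`.
#' @param ... unused.
#' @export
tidy.contrast_result <- function(x, ...) {
  tibble::tibble(
    name = if (is.null(x$name)) NA_character_ else x$name,
    t = x$t, p = x$p, df = x$df, mean_difference = x$mean_difference,
    n = length(x$per_participant_forward), corrected = x$corrected
  )
}

#' Run directional contrasts on per-participant coupling matrices
#'
#' Pools each contrast's forward/backward coupling per participant with
#' [pooled_directional_ec()] and tests the paired difference with
#' [paired_directionality_test()].
#'
#' @param ec_list list of per-participant coupling matrices (shared labels).
#' @param contrasts list of [directional_contrast()] objects (default: the
#'   six [preplanned_contrasts()]).
#' @return A tibble with one row per contrast (`name`, `t`, `p`, `df`,
#'   `mean_difference`, `n`, `corrected`).
#' @export
run_directional_contrasts <- function(ec_list,
                                      contrasts = preplanned_contrasts()) {
  rows <- purrr::map(contrasts, function(ct) {
    fb <- vapply(ec_list, pooled_directional_ec, numeric(2), contrast = ct)
    res <- paired_directionality_test(fb["forward", ], fb["backward", ],
                                      name = ct$name)
    tidy(res)
  })
  dplyr::bind_rows(rows)
}
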