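#' Heatmap of a connectivity matrix
#'
#' Displays a coupling, moment or difference matrix the way connectivity
#' matrices are conventionally shown: rows are receivers, columns senders,
#' magnitudes below the display threshold blanked (white) and the colour scale
#' capped (default cap 0.14).
#'
#' @param m labelled square matrix.
#' @param threshold display threshold (entries with `|value| < threshold` are
#'   blanked); default 0.
#' @param cap colour-scale cap; values beyond `±cap` are shown at the cap.
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_connectivity_matrix <- function(m, threshold = 0, cap = 0.14,
                                     title = NULL) {
  thr <- apply_display_threshold(m, threshold)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(nrow(m)))
  df <- tibble::tibble(
    receiver = factor(rep(ids, times = ncol(m)), levels = rev(ids)),
    sender = factor(rep(ids, each = nrow(m)), levels = ids),
    value = ifelse(as.vector(thr$mask), NA_real_,
                   pmin(pmax(as.vector(thr$values), -cap), cap))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = sender, y = receiver, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-cap, cap), na.value = "white") +
    ggplot2::labs(x = "sender (column)", y = "receiver (row)", fill = NULL,
                  title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
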