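#' Load and validate a region table
#'
#' Reads a TSV with columns `name`, `hemisphere` (`L`/`R`), `group` (integer
#' 1-8 or `NA` for ungrouped regions) and `index` (position of the region in
#' matrix order; must be contiguous starting at 1). Region names must be
#' unique within hemisphere, and every name must appear exactly once in each
#' hemisphere (homologous L/R pairing).
#'
#' @param path path to the TSV file; the default is the packaged table of the
#'   30 visual cortical regions per hemisphere with their 8 groups (early
#'   visual V1-V4; retrosplenial; ventromedial VMV1-3/VVC; parahippocampal
#'   PHA1-3; hippocampal; FFC/PIT/V8; inferior temporal TE1p/TE2p; anterior
#'   temporal). Group memberships named in the source analyses are exact; the
#'   remaining roster entries are a documented reconstruction.
#' @return A tibble with columns `name`, `hemisphere`, `group`, `index`,
#'   ordered by `index`.
#' @export
load_region_table <- function(path = system.file("extdata",
                                                 "visual_regions.tsv",
                                                 package = "hopfec")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("name", "hemisphere", "group", "index")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("region table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- tab[order(tab$index), req]
  if (!all(tab$hemisphere %in% c("L", "R")))
    stop("`hemisphere` must be 'L' or 'R' (row ",
         which(!tab$hemisphere %in% c("L", "R"))[1], ")", call. = FALSE)
  for (h in c("L", "R")) {
    nm <- tab$name[tab$hemisphere == h]
    if (anyDuplicated(nm))
      stop("duplicate region name within hemisphere ", h, ": ",
           nm[duplicated(nm)][1], call. = FALSE)
  }
  ln <- sort(tab$name[tab$hemisphere == "L"])
  rn <- sort(tab$name[tab$hemisphere == "R"])
  if (!identical(ln, rn)) {
    odd <- c(setdiff(ln, rn), setdiff(rn, ln))
    stop("broken L/R pairing: region '", odd[1],
         "' present in one hemisphere only", call. = FALSE)
  }
  if (!identical(sort(as.integer(tab$index)), seq_len(nrow(tab))))
    stop("`index` must be contiguous 1..", nrow(tab), call. = FALSE)
  tibble::as_tibble(tab)
}

# internal: matrix labels "name.hemisphere" in table order
region_labels <- function(table) paste(table$name, table$hemisphere, sep = ".")

#' Mean of the two directions of a coupling matrix
#'
#' `M_ij = (ec_ij + ec_ji) / 2`: the symmetric part, i.e. the mean of the
#' column-to-row and row-to-column connectivity for every pair.
#'
#' @param ec square numeric matrix.
#' @return Symmetric matrix of the same shape.
#' @export
symmetrized_mean <- function(ec) {
  if (!is.matrix(ec) || nrow(ec) != ncol(ec))
    stop("`ec` must be a square matrix", call. = FALSE)
  (ec + t(ec)) / 2
}

#' Directional asymmetry of a coupling matrix
#'
#' `D_ij = ec_ij - ec_ji`. Since `ec_ij` is the input to `i` from `j`
#' (column-to-row), `D_ij > 0` means the connectivity is stronger from column
#' to row. The result is antisymmetric, and together with
#' [symmetrized_mean()] reconstructs the input exactly:
#' `ec = symmetrized_mean(ec) + asymmetry(ec) / 2`.
#'
#' @inheritParams symmetrized_mean
#' @return Antisymmetric matrix of the same shape.
#' @export
asymmetry <- function(ec) {
  if (!is.matrix(ec) || nrow(ec) != ncol(ec))
    stop("`ec` must be a square matrix", call. = FALSE)
  ec - t(ec)
}

#' Mask sub-threshold entries for display
#'
#' Entries with `|value| < thr` are masked (set to zero in `values`, `TRUE` in
#' `mask`); ties at the threshold are kept, matching the convention that
#' values *below* the display threshold are blanked.
#'
#' @param m numeric matrix.
#' @param thr nonnegative display threshold (e.g. 0.03 for mean effective
#'   connectivity, 0.0005 for directional differences, 0.075 for laterality
#'   differences).
#' @return List with `values` (masked matrix) and `mask` (logical matrix,
#'   `TRUE` where masked).
#' @export
apply_display_threshold <- function(m, thr) {
  if (!is.numeric(thr) || length(thr) != 1L || thr < 0)
    stop("`thr` must be a nonnegative scalar", call. = FALSE)
  mask <- abs(m) < thr
  out <- m
  out[mask] <- 0
  list(values = out, mask = mask)
}

#' Density-matched threshold for a connectivity matrix
#'
#' Returns the smallest threshold `t` such that the fraction of off-diagonal
#' entries with `|value| >= t` does not exceed `target_density`, so a
#' functional-connectivity matrix can be displayed at the same sparseness as a
#' thresholded effective-connectivity matrix (e.g. density 0.087).
#'
#' @param fc square numeric matrix.
#' @param target_density fraction of off-diagonal entries to keep, in
#'   `(0, 1]`.
#' @return List with `threshold` and `achieved_density`.
#' @export
density_matched_threshold <- function(fc, target_density) {
  if (!is.matrix(fc) || length(fc) == 0)
    stop("`fc` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(target_density) || target_density <= 0 || target_density > 1)
    stop("`target_density` must be in (0, 1]", call. = FALSE)
  v <- abs(offdiag(fc))
  m <- length(v)
  if (target_density == 1) {
    return(list(threshold = 0, achieved_density = 1))
  }
  # smallest candidate whose kept fraction does not exceed the target
  for (t in sort(unique(v))) {
    frac <- mean(v >= t)
    if (frac <= target_density)
      return(list(threshold = t, achieved_density = frac))
  }
  warning("requested density keeps no entries; threshold set above the maximum",
          call. = FALSE)
  list(threshold = max(v) * (1 + 1e-12) + .Machine$double.eps,
       achieved_density = 0)
}

#' Right-minus-left laterality difference over homologous pairs
#'
#' For every homologous region pair `(i, j)` the difference of the
#' within-hemisphere connectivity blocks is returned:
#' `out[i, j] = fc(R_i, R_j) - fc(L_i, L_j)`. Cross-hemisphere entries are not
#' compared. Row/column names of `fc_full` must be the `name.hemisphere`
#' labels of the table (in any order).
#'
#' @param fc_full connectivity matrix over both hemispheres, labelled
#'   `name.L` / `name.R`.
#' @param table a region table from [load_region_table()].
#' @return Matrix over region names (one entry per homologous pair of pairs).
#' @export
laterality_difference <- function(fc_full, table) {
  labs <- rownames(fc_full)
  if (is.null(labs) || !identical(labs, colnames(fc_full)))
    stop("`fc_full` must carry identical row/column labels", call. = FALSE)
  nms <- unique(table$name)
  lab_l <- paste(nms, "L", sep = ".")
  lab_r <- paste(nms, "R", sep = ".")
  missing <- c(lab_l, lab_r)[!(c(lab_l, lab_r) %in% labs)]
  if (length(missing) > 0)
    stop("region '", missing[1], "' not present in the matrix: unpaired region",
         call. = FALSE)
  out <- fc_full[lab_r, lab_r] - fc_full[lab_l, lab_l]
  dimnames(out) <- list(nms, nms)
  out
}
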