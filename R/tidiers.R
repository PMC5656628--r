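#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CBC matrix into one row per taxon pair
#'
#' @param x A [cbc_matrix()].
#' @param ... Unused.
#' @return A tibble: `taxon1`, `taxon2`, `n_cbc`, `n_hcbc`, and list
#'   columns `cbc_ids`, `hcbc_ids`.
#' @export
tidy.cbc_matrix <- function(x, ...) {
  combos <- utils::combn(x$taxa, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    t1 <- combos[1, k]; t2 <- combos[2, k]
    tibble::tibble(taxon1 = t1, taxon2 = t2,
                   n_cbc = x$cbc[t1, t2], n_hcbc = x$hcbc[t1, t2],
                   cbc_ids = list(x$cbc_ids[[t1, t2]]),
                   hcbc_ids = list(x$hcbc_ids[[t1, t2]]))
  })
}

#' @rdname tidy.cbc_matrix
#' @export
glance.cbc_matrix <- function(x, ...) {
  ut <- upper.tri(x$cbc)
  tibble::tibble(n_taxa = length(x$taxa),
                 n_consensus_pairs = nrow(x$pairs),
                 n_pairs_with_cbc = sum(x$cbc[ut] > 0),
                 max_cbc = max(x$cbc[ut]),
                 max_hcbc = max(x$hcbc[ut]))
}

#' Tidy a p-distance matrix into one row per taxon pair
#'
#' @param x A `p_distance`.
#' @param ... Unused.
#' @export
tidy.p_distance <- function(x, ...) {
  combos <- utils::combn(x$taxa, 2)
  tibble::tibble(taxon1 = combos[1, ], taxon2 = combos[2, ],
                 p_dist = x$d[cbind(combos[1, ], combos[2, ])])
}

#' @rdname tidy.p_distance
#' @export
glance.p_distance <- function(x, ...) {
  ut <- upper.tri(x$d)
  tibble::tibble(n_taxa = length(x$taxa), n_sites_used = x$n_sites_used,
                 mean_dist = mean(x$d[ut]), max_dist = max(x$d[ut]),
                 deletion = x$deletion)
}

#' @export
glance.delimitation <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_distinct = sum(x$call == "distinct"),
                 n_not_separable = sum(x$call == "not-separable-by-CBC"),
                 n_same = sum(x$call == "same"))
}

#' Heatmap of pairwise CBC counts
#'
#' @param object A [cbc_matrix()].
#' @param counts `"cbc"` (default) or `"hcbc"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbc_matrix <- function(object, counts = c("cbc", "hcbc"), ...) {
  counts <- match.arg(counts)
  m <- object[[counts]]
  df <- tidyr::expand_grid(taxon1 = object$taxa, taxon2 = object$taxa)
  df$n <- m[cbind(df$taxon1, df$taxon2)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$taxon2, levels = object$taxa),
    y = factor(.data$taxon1, levels = rev(object$taxa)),
    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = toupper(counts),
                  title = sprintf("Pairwise %s counts", toupper(counts))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of pairwise p-distances
#'
#' @param object A `p_distance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.p_distance <- function(object, ...) {
  df <- tidyr::expand_grid(taxon1 = object$taxa, taxon2 = object$taxa)
  df$d <- object$d[cbind(df$taxon1, df$taxon2)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$taxon2, levels = object$taxa),
    y = factor(.data$taxon1, levels = rev(object$taxa)),
    fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "p-distance",
                  title = sprintf("p-distances (%s deletion, %d sites)",
                                  object$deletion, object$n_sites_used)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Arc diagram of a secondary structure
#'
#' Draws the sequence along the x axis with one arc per base pair; helix
#' labels from [annotate_helices()] are drawn at the midpoint of each
#' labeled helix's 5' arm.
#'
#' @param seq RNA sequence string.
#' @param db Dot-bracket string.
#' @param config A [hallmark_config()] (for helix labelling).
#' @return A ggplot.
#' @export
plot_structure_arcs <- function(seq, db, config = hallmark_config()) {
  partner <- parse_dotbracket(db, seq)
  pr <- structure_pairs(partner)
  res <- strsplit(seq_residues(seq), "")[[1]]
  arcs <- purrr::map_dfr(seq_len(nrow(pr)), function(k) {
    i <- pr$i[k]; j <- pr$j[k]
    t <- seq(0, pi, length.out = 32)
    tibble::tibble(pair = k, x = (i + j) / 2 + (j - i) / 2 * cos(t),
                   y = (j - i) / 2 * sin(t))
  })
  ann <- annotate_helices(partner, config)
  labs <- dplyr::filter(ann$helices, !is.na(.data$label))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = arcs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$pair),
                       linewidth = 0.3, colour = "grey30")
  if (nrow(labs) > 0L) {
    p <- p + ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = (.data$arm5_start + .data$arm5_end) / 2, y = -3,
                   label = .data$label),
      size = 3, colour = "firebrick")
  }
  p + ggplot2::annotate("text", x = seq_along(res), y = 0, label = res,
                        size = 1.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
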