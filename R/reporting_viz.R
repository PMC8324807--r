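# PAM-pattern summaries: max-normalized 16x16 heatmap, information-content
# sequence logo, and the PAM wheel (prefix-tree sunburst weighted by
# enrichment factor), plus tabular report output.

#' Max-normalized PAM efficiency heatmap matrix
#'
#' Arranges per-PAM efficiencies as a 16 x 16 grid — rows are the first two
#' PAM bases, columns the last two, both in A,C,G,T lexicographic order —
#' and normalizes to the highest efficiency so the hottest cell is exactly 1.
#' PAMs absent from the table enter as 0 and are flagged in the `mask`
#' attribute.
#'
#' @param stats A `pam_stats` table (4-base PAMs).
#' @return A `heatmap_matrix`: 16 x 16 numeric matrix in `[0, 1]` with
#'   attributes `norm_constant` (the maximum efficiency) and `mask` (logical
#'   matrix, `TRUE` where the PAM was missing/undefined).
#' @export
heatmap_matrix <- function(stats) {
  if (!nrow(stats)) stop("stats table is empty", call. = FALSE)
  stopifnot(all(nchar(stats$pam) == 4L))
  duos <- enumerate_pams(2)
  m <- matrix(0, 16L, 16L, dimnames = list(duos, duos))
  mask <- matrix(TRUE, 16L, 16L, dimnames = list(duos, duos))
  eff <- stats$efficiency
  ok <- !is.na(eff)
  r <- substr(stats$pam, 1L, 2L)
  co <- substr(stats$pam, 3L, 4L)
  m[cbind(r[ok], co[ok])] <- eff[ok]
  mask[cbind(r[ok], co[ok])] <- FALSE
  mx <- max(m)
  if (mx > 0) m <- m / mx else warning("all efficiencies are zero")
  structure(m, class = c("heatmap_matrix", class(m)),
            norm_constant = mx, mask = mask)
}

#' Position frequency / information-content matrix for a PAM set
#'
#' Computes, per PAM position, the (optionally weighted) base frequencies
#' `f(b, i)`, the Shannon information content
#' `IC_i = 2 + sum_b f log2 f` (bits; `0 log 0 = 0`), and the letter heights
#' `f(b, i) * IC_i` used to draw a sequence logo. A position fixed to one
#' base carries 2 bits; a uniformly free position carries 0.
#'
#' @param pams Character vector of equal-length PAM sequences.
#' @param weights Optional non-negative weights (e.g. enrichment factors),
#'   default 1 per PAM.
#' @return A `logo_matrix` list: `freq` (4 x k), `ic` (length k),
#'   `heights` (4 x k).
#' @examples
#' lm <- logo_matrix(grep("^.GG.$", enumerate_pams(4), value = TRUE))
#' lm$ic  # 0 2 2 0
#' @export
logo_matrix <- function(pams, weights = NULL) {
  if (!length(pams)) stop("pams must be non-empty", call. = FALSE)
  pams <- toupper(pams)
  k <- unique(nchar(pams))
  stopifnot(length(k) == 1L)
  if (is.null(weights)) weights <- rep(1, length(pams))
  if (length(weights) != length(pams) || any(weights < 0))
    stop("weights must be non-negative, one per PAM", call. = FALSE)
  if (sum(weights) <= 0)
    stop("weights must not be all zero", call. = FALSE)
  w <- weights / sum(weights)
  freq <- matrix(0, 4L, k, dimnames = list(DNA_BASES, seq_len(k)))
  for (i in seq_len(k)) {
    b <- substr(pams, i, i)
    freq[, i] <- vapply(DNA_BASES, function(bb) sum(w[b == bb]), numeric(1))
  }
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp(freq))
  heights <- sweep(freq, 2, ic, `*`)
  structure(list(freq = freq, ic = ic, heights = heights),
            class = "logo_matrix")
}

#' PAM wheel prefix tree
#'
#' Builds the concentric-ring (sunburst) representation of a weighted PAM
#' set: ring r holds all observed length-r prefixes, each node's angular
#' span is proportional to the summed weight (typically the enrichment
#' factor) of its member PAMs, and children partition their parent's span.
#' Position 1 is the innermost ring; the root spans the full `2*pi`.
#'
#' @param ef Named non-negative vector, PAM -> weight (e.g. enrichment
#'   factor); zero-weight PAMs are dropped.
#' @return A `wheel_node` tree: each node is a list `prefix`, `weight`,
#'   `start`, `span` (radians) and `children` (named list).
#' @export
pam_wheel_tree <- function(ef) {
  if (!length(ef) || is.null(names(ef)))
    stop("ef must be a named PAM -> weight vector", call. = FALSE)
  ef <- ef[!is.na(ef) & ef > 0]
  if (!length(ef))
    stop("at least one positive weight is required", call. = FALSE)
  pams <- toupper(names(ef))
  k <- unique(nchar(pams))
  stopifnot(length(k) == 1L)
  build <- function(prefix, members, start, span) {
    node <- list(prefix = prefix, weight = sum(ef[members]),
                 start = start, span = span, children = list())
    d <- nchar(prefix)
    if (d < k) {
      at <- start
      for (b in DNA_BASES) {
        sub <- members[substr(members, d + 1L, d + 1L) == b]
        if (!length(sub)) next
        w <- sum(ef[sub]) / node$weight
        child <- build(paste0(prefix, b), sub, at, span * w)
        node$children[[b]] <- child
        at <- at + span * w
      }
    }
    node
  }
  structure(build("", names(ef), 0, 2 * pi), class = "wheel_node")
}

#' Flatten a PAM wheel tree into arc segments
#'
#' @param tree A `wheel_node` from [pam_wheel_tree()].
#' @return data.frame `(prefix, depth, start, span, weight)`, one row per
#'   non-root node; `depth` is the ring index (1 = innermost).
#' @export
wheel_segments <- function(tree) {
  rows <- list()
  walk <- function(node) {
    if (nzchar(node$prefix))
      rows[[length(rows) + 1L]] <<- data.frame(
        prefix = node$prefix, depth = nchar(node$prefix),
        start = node$start, span = node$span, weight = node$weight,
        stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  do.call(rbind, rows)
}

#' Plot PAM-pattern summaries
#'
#' `plot_heatmap()` draws the max-normalized 16 x 16 efficiency grid;
#' `plot_logo()` draws the information-content sequence logo (stacked letter
#' heights summing to each column's IC); `plot_wheel()` draws the PAM wheel
#' as a sunburst with position 1 innermost.
#'
#' @param m A `heatmap_matrix`.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(m) {
  df <- expand.grid(row = rownames(m), col = colnames(m),
                    stringsAsFactors = FALSE)
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = "relative\nefficiency") +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = "PAM bases 3-4", y = "PAM bases 1-2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname plot_heatmap
#' @param lm A `logo_matrix`.
#' @export
plot_logo <- function(lm) {
  k <- length(lm$ic)
  rows <- list()
  for (i in seq_len(k)) {
    h <- lm$heights[, i]
    ord <- order(h)  # small letters at the bottom
    y0 <- 0
    for (b in rownames(lm$heights)[ord]) {
      if (lm$heights[b, i] <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        pos = i, base = b, ymin = y0, ymax = y0 + lm$heights[b, i])
      y0 <- y0 + lm$heights[b, i]
    }
  }
  df <- do.call(rbind, rows)
  base_cols <- c(A = "#33A02C", C = "#1F78B4", G = "#FF7F00",
                 T = "#E31A1C")
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$pos - 0.4,
                                    xmax = .data$pos + 0.4,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$base),
                       alpha = 0.25) +
    ggplot2::geom_text(ggplot2::aes(x = .data$pos,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$base,
                                    color = .data$base,
                                    size = .data$ymax - .data$ymin),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 12)) +
    ggplot2::scale_fill_manual(values = base_cols, guide = "none") +
    ggplot2::scale_color_manual(values = base_cols) +
    ggplot2::scale_x_continuous(breaks = seq_len(k)) +
    ggplot2::coord_cartesian(ylim = c(0, 2)) +
    ggplot2::labs(x = "PAM position", y = "information content (bits)") +
    ggplot2::theme_classic()
}

#' @rdname plot_heatmap
#' @param tree A `wheel_node`.
#' @export
plot_wheel <- function(tree) {
  seg <- wheel_segments(tree)
  seg$base <- substr(seg$prefix, seg$depth, seg$depth)
  # guard against floating-point arc ends a hair beyond the circle
  seg$end <- pmin(seg$start + seg$span, 2 * pi)
  base_cols <- c(A = "#33A02C", C = "#1F78B4", G = "#FF7F00",
                 T = "#E31A1C")
  k <- max(seg$depth)
  lab <- seg[seg$depth == k & seg$span > 2 * pi / 120, ]
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start,
                                    xmax = .data$end,
                                    ymin = .data$depth - 0.95,
                                    ymax = .data$depth - 0.05,
                                    fill = .data$base),
                       color = "white", linewidth = 0.2) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$start + .data$span / 2,
                                    y = .data$depth + 0.35,
                                    label = .data$prefix),
                       size = 2.3) +
    ggplot2::scale_fill_manual(values = base_cols, name = "base") +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::xlim(0, 2 * pi) +
    ggplot2::theme_void()
}

#' Write the full report set for a screen analysis
#'
#' Writes the statistics table, heatmap matrix, logo matrix and wheel
#' segments as TSV, the three figures as PDF (vector graphics), and a
#' run-metadata JSON (package version, seed, thresholds, config hash). All
#' figures are reproducible from the TSV inputs alone.
#'
#' @param stats A `pam_stats` table.
#' @param outdir Output directory (created if absent).
#' @param seed Seed recorded in the metadata.
#' @param config Optional configuration list; its hash lands in the
#'   metadata.
#' @param logo_weights `"ef"` (default) weights the functional-PAM logo by
#'   enrichment factor; `"none"` weights uniformly.
#' @return Named character vector of written paths, invisibly.
#' @export
write_reports <- function(stats, outdir, seed = NA_integer_, config = NULL,
                          logo_weights = c("ef", "none")) {
  logo_weights <- match.arg(logo_weights)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stats = file.path(outdir, "pam_stats.tsv"))
  write_pam_stats(stats, paths[["stats"]])

  has_rows <- nrow(stats) > 0
  if (has_rows) {
    m <- heatmap_matrix(stats)
    paths[["heatmap_tsv"]] <- file.path(outdir, "heatmap_matrix.tsv")
    utils::write.table(cbind(prefix = rownames(m), as.data.frame(unclass(m))),
                       paths[["heatmap_tsv"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[["heatmap_pdf"]] <- file.path(outdir, "heatmap.pdf")
    ggplot2::ggsave(paths[["heatmap_pdf"]], plot_heatmap(m),
                    width = 6.5, height = 5.5)

    fun <- stats[stats$functional %in% TRUE, ]
    if (nrow(fun)) {
      w <- if (logo_weights == "ef") {
        ww <- fun$enrichment_factor
        ww[is.na(ww)] <- 0
        if (sum(ww) <= 0) rep(1, nrow(fun)) else ww
      } else rep(1, nrow(fun))
      lm <- logo_matrix(fun$pam, w)
      paths[["logo_tsv"]] <- file.path(outdir, "logo_matrix.tsv")
      utils::write.table(
        cbind(base = rownames(lm$freq), as.data.frame(lm$freq)),
        paths[["logo_tsv"]], sep = "\t", quote = FALSE, row.names = FALSE)
      paths[["logo_pdf"]] <- file.path(outdir, "logo.pdf")
      ggplot2::ggsave(paths[["logo_pdf"]], plot_logo(lm),
                      width = 5, height = 4)
      efw <- stats$enrichment_factor
      names(efw) <- stats$pam
      efw <- efw[stats$functional %in% TRUE]
      efw[is.na(efw)] <- 0
      if (any(efw > 0)) {
        tree <- pam_wheel_tree(efw)
        seg <- wheel_segments(tree)
        paths[["wheel_tsv"]] <- file.path(outdir, "wheel_segments.tsv")
        utils::write.table(seg, paths[["wheel_tsv"]], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths[["wheel_pdf"]] <- file.path(outdir, "wheel.pdf")
        ggplot2::ggsave(paths[["wheel_pdf"]], plot_wheel(tree),
                        width = 6, height = 6)
      }
    }
  }

  meta <- list(
    package = "pamscreen",
    version = as.character(utils::packageVersion("pamscreen")),
    seed = seed,
    functional_threshold = attr(stats, "functional_threshold"),
    enriched_threshold = attr(stats, "enriched_threshold"),
    ef_numerator = attr(stats, "ef_numerator"),
    logo_weights = logo_weights,
    wheel_ring_order = "position 1 innermost",
    config_hash = if (is.null(config)) NA_character_ else
      .config_hash(config)
  )
  paths[["metadata"]] <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}
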