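# Figure export: pattern heat-grids (rows = patterns sorted by frequency,
# columns = CpG index, lower panel = per-CpG combined levels) and symmetric
# Venn diagrams for 2-5 condition sets.  Plot functions draw only numbers
# handed to them; the pipeline renders figures from its exported tables.

#' Pattern heat-grid with per-CpG level panel
#'
#' Draws one row per pattern, most frequent at the top, one column per CpG
#' (filled = methylated), with a frequency bar on the right, a lower panel of
#' per-CpG combined levels, and the number of reads annotated at the bottom.
#'
#' @param patterns Character vector of pattern strings, sorted by frequency
#'   descending.
#' @param freqs Frequencies parallel to \code{patterns}.
#' @param levels Per-CpG combined levels (length = pattern width).
#' @param n_reads Optional read count annotation.
#' @param main Plot title.
#' @return Invisibly, \code{NULL}.
#' @export
plot_pattern_grid <- function(patterns, freqs, levels, n_reads = NULL, main = "") {
  stopifnot(length(patterns) == length(freqs), length(patterns) >= 1L)
  J <- nchar(patterns[1L])
  stopifnot(length(levels) == J)
  B <- pattern_matrix(patterns)
  np <- length(patterns)
  old <- par(no.readonly = TRUE)
  on.exit(par(old))
  layout(matrix(c(1L, 2L), 2L, 1L), heights = c(3, 1.3))
  par(mar = c(0.5, 4, 3, 5))
  plot(NA, xlim = c(0.5, J + 0.5), ylim = c(np + 0.5, 0.5), xaxs = "i",
       xlab = "", ylab = "pattern (frequency sorted)", axes = FALSE, main = main)
  for (i in seq_len(np)) {
    for (j in seq_len(J)) {
      rect(j - 0.5, i - 0.45, j + 0.5, i + 0.45,
           col = if (B[i, j] == 1L) "grey15" else "white", border = "grey70")
    }
  }
  axis(2, at = seq_len(np), labels = FALSE, tcl = -0.2)
  # frequency bar on the right margin
  fmax <- max(freqs)
  for (i in seq_len(np)) {
    rect(J + 0.55, i - 0.35, J + 0.55 + 1.5 * freqs[i] / fmax, i + 0.35,
         col = "steelblue", border = NA, xpd = NA)
  }
  text(J + 0.6, 0, "frequency", xpd = NA, adj = c(0, 0), cex = 0.7)
  par(mar = c(4, 4, 0.5, 5))
  barplot(levels, names.arg = seq_len(J), ylim = c(0, 1), col = "grey40",
          xlab = "CpG index", ylab = "combined level", border = NA)
  if (!is.null(n_reads)) {
    mtext(sprintf("n = %d reads", n_reads), side = 1, line = 2.6, adj = 1, cex = 0.8)
  }
  invisible(NULL)
}

#' @export
plot.pattern_fit <- function(x, ...) {
  plot_pattern_grid(names(x$freqs), unname(x$freqs), per_cpg_levels(x),
                    n_reads = x$n_reads,
                    main = if (!is.na(x$amplicon))
                      paste(x$amplicon, x$sample, sep = " / ") else "")
}

# Ellipse outline points for the symmetric Venn layouts.
venn_ellipse <- function(cx, cy, rx, ry, rot) {
  th <- seq(0, 2 * pi, length.out = 181L)
  x <- rx * cos(th)
  y <- ry * sin(th)
  cbind(cx + x * cos(rot) - y * sin(rot), cy + x * sin(rot) + y * cos(rot))
}

venn_layout <- function(k) {
  switch(as.character(k),
    "2" = list(cx = c(-0.35, 0.35), cy = c(0, 0), rx = c(0.75, 0.75),
               ry = c(0.75, 0.75), rot = c(0, 0)),
    "3" = list(cx = 0.45 * cos(pi / 2 + 2 * pi * (0:2) / 3),
               cy = 0.45 * sin(pi / 2 + 2 * pi * (0:2) / 3),
               rx = rep(0.72, 3), ry = rep(0.72, 3), rot = rep(0, 3)),
    "4" = list(cx = c(-0.25, 0.25, -0.55, 0.55), cy = c(0.12, 0.12, -0.12, -0.12),
               rx = rep(0.95, 4), ry = rep(0.55, 4),
               rot = c(pi / 4, -pi / 4, pi / 4, -pi / 4)),
    "5" = list(cx = 0.18 * cos(pi / 2 + 2 * pi * (0:4) / 5),
               cy = 0.18 * sin(pi / 2 + 2 * pi * (0:4) / 5),
               rx = rep(1.05, 5), ry = rep(0.62, 5),
               rot = pi / 2 + 2 * pi * (0:4) / 5),
    stop("venn plots support 2-5 sets"))
}

point_in_ellipse <- function(px, py, cx, cy, rx, ry, rot) {
  dx <- px - cx
  dy <- py - cy
  u <- dx * cos(-rot) - dy * sin(-rot)
  v <- dx * sin(-rot) + dy * cos(-rot)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Symmetric Venn diagram of region counts
#'
#' Draws 2-5 circles/ellipses and writes each exclusive region's count at the
#' region's centroid (located on a deterministic grid), taking the counts
#' produced by \code{\link{venn_counts}} verbatim.
#'
#' @param counts Named counts from \code{\link{venn_counts}}.
#' @param set_names Condition names in layout order; derived from the
#'   single-condition regions of \code{counts} when omitted.
#' @param main Plot title.
#' @return Invisibly, \code{NULL}.
#' @export
plot_venn <- function(counts, set_names = NULL, main = "") {
  if (is.null(set_names)) set_names <- names(counts)[!grepl("&", names(counts))]
  k <- length(set_names)
  lay <- venn_layout(k)
  plot(NA, xlim = c(-1.7, 1.7), ylim = c(-1.5, 1.5), axes = FALSE,
       xlab = "", ylab = "", asp = 1, main = main)
  cols <- c("#e41a1caa", "#377eb8aa", "#4daf4aaa", "#984ea3aa", "#ff7f00aa")
  for (i in seq_len(k)) {
    poly <- venn_ellipse(lay$cx[i], lay$cy[i], lay$rx[i], lay$ry[i], lay$rot[i])
    lines(poly, col = cols[i], lwd = 2)
  }
  # deterministic grid for region centroids
  gx <- seq(-1.6, 1.6, length.out = 241L)
  gy <- seq(-1.4, 1.4, length.out = 211L)
  gp <- expand.grid(x = gx, y = gy)
  member <- vapply(seq_len(k), function(i) {
    point_in_ellipse(gp$x, gp$y, lay$cx[i], lay$cy[i], lay$rx[i], lay$ry[i],
                     lay$rot[i])
  }, logical(nrow(gp)))
  key <- apply(member, 1L, function(m) paste(set_names[m], collapse = "&"))
  for (region in names(counts)) {
    sel <- key == region
    if (any(sel)) {
      text(mean(gp$x[sel]), mean(gp$y[sel]), counts[[region]], cex = 0.9)
    }
  }
  # label each set near its outer edge
  for (i in seq_len(k)) {
    ang <- atan2(lay$cy[i], lay$cx[i])
    r <- if (k == 2L) 1.25 else 1.45
    text(if (k == 2L) lay$cx[i] * 3.2 else r * cos(ang),
         if (k == 2L) 1.0 else r * sin(ang),
         set_names[i], cex = 0.9, font = 2)
  }
  invisible(NULL)
}

figure_device <- function(path_base, format, width = 7, height = 6) {
  if (format == "png") {
    png(paste0(path_base, ".png"), width = width, height = height,
        units = "in", res = 120)
  } else {
    svg(paste0(path_base, ".svg"), width = width, height = height)
  }
}

#' Render figures from exported pipeline tables
#'
#' Reads the distribution, per-CpG level, and Venn tables under a pipeline
#' output directory and renders the pattern grids and Venn diagrams as PNG and
#' SVG under \code{figures/}. Every number drawn comes from the tables, never
#' from recomputation.
#'
#' @param out_dir A \code{\link{run_pipeline}} output directory.
#' @param formats Subset of \code{c("png", "svg")}.
#' @return Character vector of figure paths, invisibly.
#' @export
render_reports <- function(out_dir, formats = c("png", "svg")) {
  figdir <- file.path(out_dir, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  dist_files <- list.files(file.path(out_dir, "dist"), "\\.dist\\.tsv$",
                           full.names = TRUE)
  for (f in dist_files) {
    df <- read_distribution(f)
    if (!nrow(df)) {
      warning("empty distribution table, no figure: ", f)
      next
    }
    lv <- read.delim(file.path(out_dir, "levels",
                               sub("\\.dist\\.tsv$", ".levels.tsv", basename(f))))
    base <- file.path(figdir, sub("\\.dist\\.tsv$", ".patterns", basename(f)))
    for (fmt in formats) {
      figure_device(base, fmt)
      plot_pattern_grid(df$pattern, df$est_frequency, lv$level,
                        n_reads = sum(df$observed_count),
                        main = paste(df$amplicon[1L], df$sample[1L], sep = " / "))
      dev.off()
      made <- c(made, paste0(base, ".", fmt))
    }
  }
  venn_files <- list.files(file.path(out_dir, "compare"), "^venn\\..*\\.tsv$",
                           full.names = TRUE)
  for (f in venn_files) {
    df <- read.delim(f)
    counts <- df$count
    names(counts) <- df$region
    base <- file.path(figdir, sub("\\.tsv$", "", basename(f)))
    for (fmt in formats) {
      figure_device(base, fmt, width = 6, height = 6)
      plot_venn(counts, main = sub("\\.tsv$", "", basename(f)))
      dev.off()
      made <- c(made, paste0(base, ".", fmt))
    }
  }
  invisible(made)
}
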