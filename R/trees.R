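#' Convert a correlation matrix to a distance matrix
#'
#' Elementwise `d = 1 - CC` with an exactly zero diagonal. Since CC is in
#' \[-1, 1\], distances lie in \[0, 2\].
#'
#' @param m Correlation matrix (symmetric, unit diagonal, dimnames set).
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
cc_to_distance <- function(m) {
  if (!isSymmetric(unname(as.matrix(m)))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  d <- 1 - as.matrix(m)
  diag(d) <- 0
  d
}

#' Build a tree from a distance matrix
#'
#' UPGMA and WPGMA produce rooted ultrametric trees (arithmetic i.e.
#' group-size-weighted vs. simple averaging of cluster distances, via
#' [phangorn::upgma()] / [phangorn::wpgma()]); NJ produces an unrooted tree
#' by the standard Q-criterion ([ape::nj()]), with any negative branch
#' lengths clamped to zero with a warning.
#'
#' @param d Symmetric non-negative distance matrix (zero diagonal) or a
#'   `dist` object; typically `cc_to_distance(cc_matrix(...))`.
#' @param method `"upgma"` (default), `"wpgma"` or `"nj"`.
#' @return An [ape::phylo] tree with a logical `rooted` attribute.
#' @export
build_tree <- function(d, method = c("upgma", "wpgma", "nj")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric",
                                     call. = FALSE)
  if (any(dm < 0)) stop("negative distances not allowed", call. = FALSE)
  if (nrow(dm) < 2L) stop(">= 2 species required", call. = FALSE)
  dd <- stats::as.dist(dm)
  tree <- switch(method,
    upgma = phangorn::upgma(dd),
    wpgma = phangorn::wpgma(dd),
    nj = ape::nj(dd)
  )
  if (method == "nj" && any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "rooted") <- method %in% c("upgma", "wpgma")
  tree
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @param digits Branch-length precision (default 6 decimal digits).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Leaf order of a tree (left-to-right display order)
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of tip labels in cladewise order.
#' @export
leaf_order <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$edge[, 2L][tree$edge[, 2L] <= length(tree$tip.label)]
  tree$tip.label[tips]
}

#' Reorder a correlation matrix to a tree's leaf order
#'
#' Permutes rows and columns so that adjacent rows are close on the tree —
#' the standard preparation for heatmap rendering.
#'
#' @param m Correlation matrix.
#' @param tree An [ape::phylo] tree whose tips are exactly the matrix's
#'   species.
#' @return The permuted matrix.
#' @export
ordered_matrix <- function(m, tree) {
  ord <- leaf_order(tree)
  if (!setequal(ord, rownames(m))) {
    stop("tree leaves and matrix species differ", call. = FALSE)
  }
  m[ord, ord]
}

#' Render a correlation heatmap to PNG
#'
#' Monotone color ramp from low (dark red) to high (light yellow) CC,
#' rows/columns in the supplied matrix order.
#'
#' @param m Correlation matrix (typically from [ordered_matrix()]).
#' @param path PNG output path.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
plot_cc_heatmap <- function(m, path, width = 800, height = 800) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("darkred", "red", "orange",
                                       "yellow", "lightyellow"))(100)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(path)
}
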