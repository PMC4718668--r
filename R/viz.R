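#' Network rendering and graph export
#'
#' Networks are drawn in pseudoanatomical space: one node per region at its
#' fixed registry layout coordinate, edges as straight lines styled by the
#' field's visual grammar - black for positive correlations, red for
#' negative, line width proportional to |r|, node border colored by
#' community membership. Difference maps draw only significant edges, solid
#' for gains and dashed for losses. Rendering writes SVG directly as text,
#' so identical inputs produce byte-identical files.
#'
#' @name viz_export
NULL

#' Rendering style
#'
#' @param positive_color,negative_color edge colors for positive/negative
#'   weights (default black / red).
#' @param width_min,width_max stroke widths mapped linearly onto |r| in
#'   [0, 1]: width = width_min + (width_max - width_min) * |r|.
#' @param community_palette colors cycled over community labels in label
#'   order for node borders.
#' @param node_radius,node_fill node geometry.
#' @return a `render_style` list.
#' @export
render_style <- function(positive_color = "#000000",
                         negative_color = "#CC0000",
                         width_min = 0.6, width_max = 4.2,
                         community_palette = c(
                           "#1B9E77", "#D95F02", "#7570B3", "#E7298A",
                           "#66A61E", "#E6AB02", "#A6761D", "#666666",
                           "#1F78B4", "#B2DF8A", "#FB9A99", "#CAB2D6"),
                         node_radius = 16, node_fill = "#FFFFFF") {
  structure(list(positive_color = positive_color,
                 negative_color = negative_color,
                 width_min = width_min, width_max = width_max,
                 community_palette = community_palette,
                 node_radius = node_radius, node_fill = node_fill),
            class = "render_style")
}

edge_width <- function(style, r) {
  style$width_min + (style$width_max - style$width_min) * abs(r)
}

fmt <- function(x) sprintf("%.2f", x)

svg_canvas <- function(registry, pad = 60, scale = 70) {
  x <- (registry$x - min(registry$x)) * scale + pad
  # flip y: larger layout y means nearer the top of the figure
  y <- (max(registry$y) - registry$y) * scale + pad
  list(x = x, y = y,
       width = max(x) + pad, height = max(y) + pad + 40)
}

svg_header <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            fmt(width), fmt(height), fmt(width), fmt(height)))
}

svg_nodes <- function(registry, canvas, style, border_color) {
  unlist(lapply(seq_len(nrow(registry)), function(i) {
    c(sprintf(paste0('<circle class="node" cx="%s" cy="%s" r="%s" ',
                     'fill="%s" stroke="%s" stroke-width="3"/>'),
              fmt(canvas$x[i]), fmt(canvas$y[i]), fmt(style$node_radius),
              style$node_fill, border_color[i]),
      sprintf(paste0('<text class="label" x="%s" y="%s" ',
                     'text-anchor="middle" font-family="sans-serif" ',
                     'font-size="9">%s</text>'),
              fmt(canvas$x[i]), fmt(canvas$y[i] + 3),
              registry$region_id[i]))
  }))
}

svg_edge <- function(x1, y1, x2, y2, color, width, dashed = FALSE,
                     class = "edge") {
  dash <- if (dashed) ' stroke-dasharray="8,6"' else ""
  sprintf(paste0('<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" ',
                 'stroke="%s" stroke-width="%s"%s/>'),
          class, fmt(x1), fmt(y1), fmt(x2), fmt(y2), color, fmt(width),
          dash)
}

#' Render a thresholded network as SVG
#'
#' @param net a `thresholded_network`.
#' @param partition a `community_partition` covering the same regions (or
#'   NULL for uncolored borders).
#' @param registry region registry with layout coordinates.
#' @param path output SVG path.
#' @param style a [render_style()].
#' @return `path`, invisibly.
#' @export
render_network <- function(net, partition = NULL,
                           registry = default_region_registry(),
                           path, style = render_style()) {
  stopifnot(inherits(net, "thresholded_network"))
  reg <- registry[match(net$regions, registry$region_id), , drop = FALSE]
  if (anyNA(reg$region_id)) {
    stop("MissingLayout: network region absent from registry", call. = FALSE)
  }
  canvas <- svg_canvas(reg)
  border <- rep("#888888", nrow(reg))
  if (!is.null(partition)) {
    lab <- partition$assignment[net$regions]
    if (anyNA(lab)) {
      stop("partition does not cover every network region", call. = FALSE)
    }
    pal <- style$community_palette
    border <- pal[((lab - 1L) %% length(pal)) + 1L]
  }
  idx <- which(upper.tri(net$w) & net$w != 0, arr.ind = TRUE)
  edges <- character(0)
  if (nrow(idx) > 0L) {
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    edges <- vapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      r <- net$w[i, j]
      svg_edge(canvas$x[i], canvas$y[i], canvas$x[j], canvas$y[j],
               if (r > 0) style$positive_color else style$negative_color,
               edge_width(style, r))
    }, "")
  }
  title <- sprintf(
    paste0('<text x="%s" y="%s" font-family="sans-serif" ',
           'font-size="13">%s (alpha = %g, n = %d)</text>'),
    fmt(20), fmt(canvas$height - 15),
    group_label(net$gene, net$age, net$treatment), net$alpha, net$n)
  lines <- c(svg_header(canvas$width, canvas$height), edges,
             svg_nodes(reg, canvas, style, border), title, "</svg>")
  write_svg(lines, path)
}

DIFF_CLASS_STYLE <- list(
  gain_positive = list(color = "positive", dashed = FALSE),
  loss_positive = list(color = "positive", dashed = TRUE),
  gain_negative = list(color = "negative", dashed = FALSE),
  loss_negative = list(color = "negative", dashed = TRUE),
  sign_reversal = list(color = "reversal", dashed = FALSE)
)

#' Render a difference map as SVG
#'
#' Only significant edges are drawn: solid for gains, dashed for losses,
#' black for positive-CGE classes and red for negative-CGE classes (sign
#' reversals in purple). A legend of the classes present is embedded.
#'
#' @param diff a `difference_map`.
#' @param registry region registry with layout coordinates.
#' @param path output SVG path.
#' @param style a [render_style()].
#' @return `path`, invisibly.
#' @export
render_difference_map <- function(diff,
                                  registry = default_region_registry(),
                                  path, style = render_style()) {
  stopifnot(inherits(diff, "difference_map"))
  reg <- registry
  canvas <- svg_canvas(reg)
  color_of <- c(positive = style$positive_color,
                negative = style$negative_color,
                reversal = "#7B2D8E")
  sig <- diff[diff$significant & diff$class != "none", , drop = FALSE]
  edges <- character(0)
  if (nrow(sig) > 0L) {
    sig <- sig[order(sig$region_a, sig$region_b, method = "radix"), ,
               drop = FALSE]
    ia <- match(sig$region_a, reg$region_id)
    ib <- match(sig$region_b, reg$region_id)
    edges <- vapply(seq_len(nrow(sig)), function(k) {
      st <- DIFF_CLASS_STYLE[[sig$class[k]]]
      dr <- max(abs(sig$r_a[k]), abs(sig$r_b[k]))
      svg_edge(canvas$x[ia[k]], canvas$y[ia[k]],
               canvas$x[ib[k]], canvas$y[ib[k]],
               color_of[[st$color]], edge_width(style, dr),
               dashed = st$dashed, class = "diff-edge")
    }, "")
  }
  legend_classes <- intersect(names(DIFF_CLASS_STYLE), unique(sig$class))
  legend <- unlist(lapply(seq_along(legend_classes), function(k) {
    cls <- legend_classes[k]
    st <- DIFF_CLASS_STYLE[[cls]]
    y <- 18 * k
    c(svg_edge(canvas$width - 170, y, canvas$width - 130, y,
               color_of[[st$color]], 2.5, dashed = st$dashed,
               class = "legend-edge"),
      sprintf(paste0('<text class="legend" x="%s" y="%s" ',
                     'font-family="sans-serif" font-size="10">%s</text>'),
              fmt(canvas$width - 124), fmt(y + 3), cls))
  }))
  title <- sprintf(
    paste0('<text x="%s" y="%s" font-family="sans-serif" ',
           'font-size="13">%s vs %s (q = %g)</text>'),
    fmt(20), fmt(canvas$height - 15), attr(diff, "group_a"),
    attr(diff, "group_b"), attr(diff, "q_level"))
  border <- rep("#888888", nrow(reg))
  lines <- c(svg_header(canvas$width, canvas$height), edges,
             svg_nodes(reg, canvas, render_style(), border),
             legend, title, "</svg>")
  write_svg(lines, path)
}

write_svg <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Export a network or difference map to a standard graph format
#'
#' Formats: `"graphml"` (via igraph, with weight/sign attributes, plus
#' p/q/class for difference maps and community labels when a partition is
#' supplied), `"edgelist"` (TSV `region_a, region_b, weight, sign[, p,
#' q_adj, class]`), `"csv"` (square weight matrix, identical to
#' [write_square_csv()] of the thresholded matrix).
#'
#' @param x a `thresholded_network` or `difference_map`.
#' @param path output path.
#' @param format one of `"graphml"`, `"edgelist"`, `"csv"`.
#' @param partition optional `community_partition` (graphml node
#'   attribute).
#' @return `path`, invisibly.
#' @export
export_graph <- function(x, path, format = c("graphml", "edgelist", "csv"),
                         partition = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("UnsupportedFormat: ", format[1L],
                            call. = FALSE))
  if (inherits(x, "thresholded_network")) {
    el <- network_edge_list(x)
    regions <- x$regions
    w <- x$w
  } else if (inherits(x, "difference_map")) {
    sig <- x[x$significant, , drop = FALSE]
    el <- data.frame(region_a = sig$region_a, region_b = sig$region_b,
                     weight = sig$Z, sign = ifelse(sig$Z >= 0, 1L, -1L),
                     p = sig$p, q_adj = sig$q_adj, class = sig$class,
                     stringsAsFactors = FALSE)
    regions <- sort(unique(c(x$region_a, x$region_b)))
    w <- NULL
  } else {
    stop("export_graph needs a thresholded_network or difference_map",
         call. = FALSE)
  }
  if (format == "csv") {
    if (is.null(w)) {
      stop("UnsupportedFormat: square CSV export applies to networks only",
           call. = FALSE)
    }
    return(write_square_csv(w, path))
  }
  if (format == "edgelist") {
    out <- el
    num <- vapply(out, is.numeric, TRUE) & names(out) != "sign"
    out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = regions))
  if (!is.null(partition)) {
    igraph::V(g)$community <- as.integer(partition$assignment[regions])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

network_edge_list <- function(net) {
  idx <- which(upper.tri(net$w) & net$w != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(region_a = net$regions[idx[, 1L]],
             region_b = net$regions[idx[, 2L]],
             weight = net$w[idx],
             sign = ifelse(net$w[idx] >= 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Read a TSV edge list written by [export_graph()]
#'
#' @param path file path.
#' @return data frame of edges.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
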