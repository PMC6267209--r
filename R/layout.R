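# Layer-banded layouts. Layer i of k occupies its own region of the canvas:
# in 2D the horizontal band y in [i-1+m, i-m] (band margin m = 0.1, so bands
# of distinct layers never touch), in 3D the plane z = i. The scaled variant
# is pure arithmetic (bit-identical across runs); the random variant draws
# within-band positions uniformly under a minimum-separation constraint and
# is reproducible from its seed.

BAND_MARGIN <- 0.1

layer_band <- function(i, dims) {
  if (dims == 2L) c(lower = i - 1 + BAND_MARGIN, upper = i - BAND_MARGIN)
  else c(lower = i, upper = i)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

nodes_by_layer <- function(g) {
  lapply(g$layers$id, function(lid) {
    names(g$nodes)[vapply(g$nodes, function(n) n$layer_id == lid, logical(1))]
  })
}

make_layout <- function(g, kind, seed, rows, dims) {
  coords <- do.call(rbind, rows)
  if (is.null(coords)) {
    coords <- data.frame(name = character(), layer_id = integer(),
                         x = numeric(), y = numeric(), stringsAsFactors = FALSE)
    if (dims == 3L) coords$z <- numeric()
  }
  rownames(coords) <- NULL
  bands <- t(vapply(g$layers$id, layer_band, numeric(2), dims = dims))
  structure(list(
    kind = kind,
    seed = seed,
    coords = coords,
    layer_bands = data.frame(layer_id = g$layers$id,
                             lower = unname(bands[, 1L]),
                             upper = unname(bands[, 2L]))
  ), class = "mlgraph_layout")
}

#' Deterministic scaled layer-banded layout
#'
#' Divides each layer's display area evenly among its nodes so that no two
#' vertices overlap. In 2D, layer `i` (of `k`) occupies the horizontal band
#' `y` in `[i-1+0.1, i-0.1]`; its `n` nodes sit at `x = (j-0.5)/n` (insertion
#' order, `j = 1..n`) on the band midline. In 3D, layer `i` is the plane
#' `z = i` and its nodes occupy a centred square grid of side
#' `ceiling(sqrt(n))` with unit spacing. Pure arithmetic: repeated calls give
#' bit-identical coordinates.
#'
#' @param g An `mlgraph` with at least one layer.
#' @param dims 2 or 3.
#' @return An object of class `mlgraph_layout`: `kind`, `seed` (`NULL` here),
#'   `coords` (data frame `name`, `layer_id`, `x`, `y`\[, `z`\]) and
#'   `layer_bands` (data frame `layer_id`, `lower`, `upper`).
#' @export
layout_scaled <- function(g, dims = 2) {
  assert_mlgraph(g)
  dims <- check_dims(dims)
  if (nrow(g$layers) == 0L) err_validation("cannot lay out a graph with no layers")
  groups <- nodes_by_layer(g)
  rows <- list()
  for (i in seq_along(groups)) {
    nms <- groups[[i]]
    n <- length(nms)
    if (n == 0L) next
    lid <- g$layers$id[i]
    if (dims == 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = nms, layer_id = lid,
        x = (seq_len(n) - 0.5) / n,
        y = rep(lid - 0.5, n),
        stringsAsFactors = FALSE)
    } else {
      s <- ceiling(sqrt(n))
      j <- seq_len(n) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = nms, layer_id = lid,
        x = (j %% s) - (s - 1) / 2,
        y = (j %/% s) - (s - 1) / 2,
        z = rep(as.numeric(lid), n),
        stringsAsFactors = FALSE)
    }
  }
  make_layout(g, if (dims == 2L) "scaled2d" else "scaled3d", NULL, rows, dims)
}

#' Seeded random layer-banded layout
#'
#' Same bands/planes as [layout_scaled()], but within-band positions are drawn
#' uniformly (x in \[0, 1\], and in 2D y across the band; in 3D x, y in
#' \[0, 1\]² on the plane `z = i`). Positions are resampled until every pair
#' of nodes in a layer is at least `epsilon` apart, so vertices never overlap;
#' if a band is too crowded to satisfy the separation within `max_resample`
#' draws, a capacity error advises the scaled layout. Reproducible: the same
#' seed gives the same coordinates.
#'
#' @param g An `mlgraph` with at least one layer.
#' @param dims 2 or 3.
#' @param seed Integer RNG seed (default 42); the session RNG is not disturbed.
#' @param epsilon Minimum within-layer pairwise distance (default 0.05).
#' @param max_resample Resampling budget per layer (default 1000).
#' @return An `mlgraph_layout` (see [layout_scaled()]).
#' @export
layout_random <- function(g, dims = 2, seed = 42L, epsilon = 0.05,
                          max_resample = 1000L) {
  assert_mlgraph(g)
  dims <- check_dims(dims)
  if (nrow(g$layers) == 0L) err_validation("cannot lay out a graph with no layers")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    err_validation("'seed' must be a single integer")
  }
  seed <- as.integer(seed)
  groups <- nodes_by_layer(g)
  rows <- with_seed(seed, {
    out <- list()
    for (i in seq_along(groups)) {
      nms <- groups[[i]]
      n <- length(nms)
      if (n == 0L) next
      lid <- g$layers$id[i]
      band <- layer_band(lid, 2L)
      pts <- matrix(numeric(0), nrow = 0L, ncol = 2L)
      tries <- 0L
      for (j in seq_len(n)) {
        repeat {
          cand <- if (dims == 2L) {
            c(stats::runif(1), stats::runif(1, band["lower"], band["upper"]))
          } else {
            stats::runif(2)
          }
          ok <- nrow(pts) == 0L ||
            min(sqrt((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2)) >= epsilon
          if (ok) break
          tries <- tries + 1L
          if (tries > max_resample) {
            err_capacity(sprintf(
              "layer '%s' is too crowded for separation %g; use layout_scaled()",
              g$layers$name[i], epsilon))
          }
        }
        pts <- rbind(pts, cand)
      }
      out[[length(out) + 1L]] <- if (dims == 2L) {
        data.frame(name = nms, layer_id = lid, x = unname(pts[, 1L]),
                   y = unname(pts[, 2L]), stringsAsFactors = FALSE)
      } else {
        data.frame(name = nms, layer_id = lid, x = unname(pts[, 1L]),
                   y = unname(pts[, 2L]), z = rep(as.numeric(lid), n),
                   stringsAsFactors = FALSE)
      }
    }
    out
  })
  make_layout(g, if (dims == 2L) "random2d" else "random3d", seed, rows, dims)
}

check_dims <- function(dims) {
  if (!is.numeric(dims) || length(dims) != 1L || !dims %in% c(2, 3)) {
    err_validation("'dims' must be 2 or 3")
  }
  as.integer(dims)
}

#' @export
print.mlgraph_layout <- function(x, ...) {
  cat(sprintf("mlgraph layout '%s': %d node position(s), %d layer band(s)\n",
              x$kind, nrow(x$coords), nrow(x$layer_bands)))
  invisible(x)
}

# ---- rendering (purely presentational) --------------------------------------

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

layer_palette <- function(k) {
  grDevices::hcl.colors(max(k, 2L), "Dark 3")[seq_len(k)]
}

#' Render a layout to a static picture file
#'
#' A presentation-only step: coordinates come entirely from the layout
#' object. 2D layouts are written as a self-contained SVG image (nodes
#' coloured by layer, edges drawn, layer bands shaded and labelled); 3D
#' layouts as a self-contained HTML file embedding an oblique-projection SVG
#' scene with one plane per layer.
#'
#' @param g The `mlgraph` the layout was computed for.
#' @param layout An `mlgraph_layout` covering exactly the nodes of `g`.
#' @param path Output file path (conventionally `.svg` for 2D, `.html` for 3D).
#' @return Invisibly, `path`.
#' @export
render_layout <- function(g, layout, path) {
  assert_mlgraph(g)
  if (!inherits(layout, "mlgraph_layout")) {
    err_validation("'layout' must be an mlgraph_layout")
  }
  if (!setequal(layout$coords$name, names(g$nodes)) ||
      nrow(layout$coords) != length(g$nodes)) {
    err_validation("layout does not cover exactly the nodes of the graph")
  }
  content <- if (layout$kind %in% c("scaled2d", "random2d")) {
    svg_2d(g, layout)
  } else {
    html_3d(g, layout)
  }
  ok <- tryCatch({ writeLines(content, path, useBytes = TRUE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) err_io(sprintf("cannot write to '%s'", path))
  invisible(path)
}

svg_2d <- function(g, layout) {
  k <- nrow(g$layers)
  W <- 800; Hband <- 140; H <- Hband * max(k, 1L)
  pad <- 40
  sx <- function(x) pad + x * (W - 2 * pad)
  sy <- function(y) H - y * Hband   # world y grows upward
  pal <- layer_palette(k)
  co <- layout$coords
  pos <- function(nm) co[co$name == nm, , drop = FALSE]
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', W, H, W, H),
           sprintf('<rect width="%d" height="%d" fill="white"/>', W, H))
  for (i in seq_len(k)) {
    b <- layout$layer_bands[i, ]
    out <- c(out, sprintf(
      '<rect x="%g" y="%g" width="%g" height="%g" fill="%s" fill-opacity="0.10"/>',
      sx(0), sy(b$upper), sx(1) - sx(0), sy(b$lower) - sy(b$upper), pal[i]),
      sprintf('<text x="%g" y="%g" font-size="13" fill="%s">%s</text>',
              5, sy((b$lower + b$upper) / 2), pal[i],
              xml_escape(g$layers$name[i])))
  }
  for (e in g$edges) {
    p1 <- pos(e$source); p2 <- pos(e$target)
    out <- c(out, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="grey" stroke-width="1"/>',
      sx(p1$x), sy(p1$y), sx(p2$x), sy(p2$y)))
  }
  for (r in seq_len(nrow(co))) {
    out <- c(out, sprintf(
      '<circle cx="%g" cy="%g" r="6" fill="%s" stroke="black"/>',
      sx(co$x[r]), sy(co$y[r]), pal[co$layer_id[r]]),
      sprintf('<text x="%g" y="%g" font-size="10">%s</text>',
              sx(co$x[r]) + 8, sy(co$y[r]) - 8, xml_escape(co$name[r])))
  }
  c(out, "</svg>")
}

# Oblique projection of (x, y, z): depth (y) foreshortened at 0.4, z upward.
html_3d <- function(g, layout) {
  proj <- function(x, y, z) c(px = x + 0.4 * y, py = -(z + 0.4 * y))
  co <- layout$coords
  k <- nrow(g$layers)
  pal <- layer_palette(k)
  ext <- range(c(co$x, co$y, 0, 1))
  P <- if (nrow(co)) t(mapply(function(x, y, z) proj(x, y, z), co$x, co$y, co$z))
       else matrix(numeric(0), 0L, 2L)
  corners <- lapply(g$layers$id, function(i) {
    rbind(proj(ext[1], ext[1], i), proj(ext[2], ext[1], i),
          proj(ext[2], ext[2], i), proj(ext[1], ext[2], i))
  })
  allpx <- c(P[, 1], unlist(lapply(corners, function(m) m[, 1])))
  allpy <- c(P[, 2], unlist(lapply(corners, function(m) m[, 2])))
  rx <- range(allpx); ry <- range(allpy)
  W <- 800; H <- 600; pad <- 50
  mx <- function(p) pad + (p - rx[1]) / max(diff(rx), 1e-9) * (W - 2 * pad)
  my <- function(p) pad + (p - ry[1]) / max(diff(ry), 1e-9) * (H - 2 * pad)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', W, H))
  for (i in seq_len(k)) {
    m <- corners[[i]]
    pts <- paste(sprintf("%g,%g", mx(m[, 1]), my(m[, 2])), collapse = " ")
    svg <- c(svg, sprintf(
      '<polygon points="%s" fill="%s" fill-opacity="0.12" stroke="%s"/>',
      pts, pal[i], pal[i]),
      sprintf('<text x="%g" y="%g" font-size="13" fill="%s">%s</text>',
              mx(m[1, 1]), my(m[1, 2]) - 4, pal[i],
              xml_escape(g$layers$name[i])))
  }
  pos <- function(nm) { r <- which(co$name == nm); c(mx(P[r, 1]), my(P[r, 2])) }
  for (e in g$edges) {
    p1 <- pos(e$source); p2 <- pos(e$target)
    svg <- c(svg, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="grey" stroke-width="1"/>',
      p1[1], p1[2], p2[1], p2[2]))
  }
  for (r in seq_len(nrow(co))) {
    svg <- c(svg, sprintf(
      '<circle cx="%g" cy="%g" r="5" fill="%s" stroke="black"/>',
      mx(P[r, 1]), my(P[r, 2]), pal[co$layer_id[r]]))
  }
  svg <- c(svg, "</svg>")
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s — 3D layer scene</title>", xml_escape(g$name)),
    "</head><body>",
    sprintf("<h3>%s: %d layers, %d nodes</h3>", xml_escape(g$name),
            nrow(g$layers), length(g$nodes)),
    svg, "</body></html>")
}
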