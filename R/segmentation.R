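#' Resolve the segmentation rule's five bands
#'
#' The rule-based mask uses reflectance at 410, 456, 553, 654 and 852 nm
#' (abbreviated B1, B2, G, R, N). This resolves those wavelengths to band
#' indices of a given cube via nearest-wavelength lookup.
#'
#' @param cube a reflectance [spectral_cube()] covering the visible/NIR range.
#' @return `list(b1, b2, g, r, n)` of band indices (all distinct).
#' @export
rule_band_set <- function(cube) {
  idx <- list(b1 = band_at(cube, 410), b2 = band_at(cube, 456),
              g = band_at(cube, 553), r = band_at(cube, 654),
              n = band_at(cube, 852))
  if (anyDuplicated(unlist(idx)))
    stop("rule bands are not distinct on this cube's wavelength grid")
  idx
}

#' Rule-based seed/background mask
#'
#' A pixel is classed as seed (1) iff all five reflectance conditions hold:
#' B1 < B2; 0.7*B1 <= R <= 12.5*B1; 1.2*B1 <= N <= 15*B1; B2 < G; and
#' 1.2*B2 < G. Everything else (tray, panel, markers, shadow) is background
#' (0). The thresholds encode the characteristic rising visible/NIR slope of
#' seed tissue relative to the flat or falling background materials.
#'
#' @param cube reflectance [spectral_cube()].
#' @param bands band indices from [rule_band_set()] (resolved from the cube
#'   when omitted).
#' @return Integer 0/1 matrix of the cube's spatial dimensions.
#' @export
rule_mask <- function(cube, bands = rule_band_set(cube)) {
  b1 <- cube$data[, , bands$b1]; b2 <- cube$data[, , bands$b2]
  g <- cube$data[, , bands$g]; r <- cube$data[, , bands$r]
  n <- cube$data[, , bands$n]
  seed <- (b1 < b2) &
    (0.7 * b1 <= r) & (r <= 12.5 * b1) &
    (1.2 * b1 <= n) & (n <= 15 * b1) &
    (b2 < g) & (1.2 * b2 < g)
  mode(seed) <- "integer"
  seed
}

#' Morphological opening with a 3x3 structuring element
#'
#' Erosion followed by dilation with a 3x3 square kernel: removes isolated
#' noise pixels and thin protrusions while preserving solid seed bodies.
#'
#' @param mask binary 0/1 matrix.
#' @param kernel_size odd kernel side length (default 3).
#' @return Opened 0/1 integer matrix.
#' @export
morphological_open <- function(mask, kernel_size = 3L) {
  kern <- EBImage::makeBrush(kernel_size, shape = "box")
  out <- EBImage::imageData(EBImage::opening(EBImage::Image(mask), kern))
  out <- matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
  out
}

#' Repair holes inside seed regions by flood fill
#'
#' Adds a one-pixel background guard border, flood fills (4-connected) the
#' background from the top-left corner with a temporary value 2, reassigns
#' any remaining 0 pixels (holes enclosed by seed tissue) to the seed class,
#' relabels the filled background as 0 and strips the border. No input seed
#' pixel is ever removed.
#'
#' @param mask binary 0/1 matrix.
#' @return 0/1 integer matrix with interior holes filled.
#' @export
repair_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  filled <- EBImage::imageData(EBImage::floodFill(EBImage::Image(padded), c(1L, 1L), col = 2))
  out <- matrix(as.integer(filled), h + 2L, w + 2L)
  out[out == 0L] <- 1L   # unreached zeros are holes inside seeds
  out[out == 2L] <- 0L   # flooded background
  out[2:(h + 1L), 2:(w + 1L)]
}

# 8-connected labeling: EBImage's 4-connected labeling plus merging of
# diagonally adjacent labels through an adjacency graph
label_components_8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right diagonal
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left diagonal
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L & pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs)) {
    g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2L), directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(as.character(1:k), igraph::V(g)$name)),
                              name = setdiff(as.character(1:k), igraph::V(g)$name))
    memb <- igraph::components(g)$membership
    remap <- integer(k)
    remap[as.integer(names(memb))] <- memb
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  # renumber 1..n in first-appearance order
  u <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Extract connected components with an area filter
#'
#' Labels the mask with 8-connected components and retains those whose pixel
#' area lies strictly inside `(min_area, max_area)` — the window that keeps
#' single seeds while rejecting specks and fused seed pairs.
#'
#' @param mask final binary 0/1 matrix.
#' @param min_area,max_area strict area bounds in px (defaults 250 and 1500).
#' @return `list(components =, labels =)`: a data frame with one row per
#'   retained component (`component_id`, `area`, `xmin/xmax/ymin/ymax` bbox,
#'   `centroid_x`, `centroid_y`, 0-based) and the full label matrix (dropped
#'   components still labeled, for diagnostics).
#' @export
extract_components <- function(mask, min_area = 250, max_area = 1500) {
  lab <- label_components_8(mask)
  k <- max(lab)
  rows <- list()
  for (id in seq_len(k)) {
    px <- which(lab == id, arr.ind = TRUE)
    area <- nrow(px)
    if (area <= min_area || area >= max_area) next
    rows[[length(rows) + 1L]] <- data.frame(
      component_id = id, area = area,
      xmin = min(px[, 2L]) - 1L, xmax = max(px[, 2L]) - 1L,
      ymin = min(px[, 1L]) - 1L, ymax = max(px[, 1L]) - 1L,
      centroid_x = mean(px[, 2L]) - 1, centroid_y = mean(px[, 1L]) - 1)
  }
  comps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component_id = integer(0), area = integer(0),
               xmin = integer(0), xmax = integer(0), ymin = integer(0),
               ymax = integer(0), centroid_x = numeric(0), centroid_y = numeric(0))
  list(components = comps, labels = lab)
}

#' Assign grid labels to components
#'
#' Seeds are laid out on a rows x cols grid of troughs; components are
#' clustered into grid rows by their centroid y (1-D clustering with a gap
#' tolerance of half the median component height), ordered by x within each
#' row, and labeled column-letter + row-number ("A1" ... "D6" for the default
#' 4-wide, 6-long tray).
#'
#' @param components component data frame from [extract_components()].
#' @param rows,cols grid dimensions (defaults 6 and 4).
#' @return The data frame with a `grid_label` column appended.
#' @export
grid_label <- function(components, rows = 6L, cols = 4L) {
  n <- nrow(components)
  if (n > rows * cols) stop("more components (", n, ") than grid cells (", rows * cols, ")")
  if (n == 0L) { components$grid_label <- character(0); return(components) }
  heights <- components$ymax - components$ymin + 1
  tol <- max(stats::median(heights) / 2, 1)
  ord <- order(components$centroid_y)
  y <- components$centroid_y[ord]
  row_id <- cumsum(c(1, diff(y) > tol))
  if (max(row_id) > rows) stop("centroids cluster into ", max(row_id),
                               " rows; grid declares ", rows)
  labels <- character(n)
  for (rid in unique(row_id)) {
    members <- ord[row_id == rid]
    members <- members[order(components$centroid_x[members])]
    if (length(members) > cols) stop("row ", rid, " holds more components than columns")
    labels[members] <- paste0(LETTERS[seq_along(members)], rid)
  }
  components$grid_label <- labels
  components
}

#' Crop a single seed from a cube
#'
#' Cuts a square window centered on the component centroid, zero-padding
#' where the window extends past the frame, and zeroes every pixel not
#' belonging to the component so the crop holds only seed signal.
#'
#' @param cube [spectral_cube()] the component was segmented from.
#' @param component one row of a component data frame.
#' @param labels label matrix from [extract_components()].
#' @param size crop side length in px (default 32).
#' @return A `seed_crop` list: `patch` (size x size x bands array), `mask`
#'   (size x size), `component_id`, `grid_label` if present.
#' @export
crop_seed <- function(cube, component, labels, size = 32L) {
  d <- dim(cube$data)
  cy <- round(component$centroid_y); cx <- round(component$centroid_x)
  half <- size %/% 2L
  rows_out <- (cy - half):(cy + half - 1L) + 1L  # 1-based frame rows
  cols_out <- (cx - half):(cx + half - 1L) + 1L
  patch <- array(0, dim = c(size, size, d[3L]))
  mask <- matrix(0L, size, size)
  rin <- rows_out >= 1L & rows_out <= d[1L]
  cin <- cols_out >= 1L & cols_out <= d[2L]
  sel <- labels[rows_out[rin], cols_out[cin], drop = FALSE] == component$component_id
  sub <- cube$data[rows_out[rin], cols_out[cin], , drop = FALSE] *
    array(sel, dim = c(sum(rin), sum(cin), d[3L]))
  patch[which(rin), which(cin), ] <- sub
  mask[which(rin), which(cin)] <- sel * 1L
  structure(list(patch = patch, mask = mask,
                 component_id = component$component_id,
                 grid_label = if ("grid_label" %in% names(component)) component$grid_label else NA_character_,
                 wavelengths = cube$wavelengths),
            class = "seed_crop")
}

#' Three-band RGB composite of a cube
#'
#' Picks the bands nearest 642 nm (red), 546 nm (green) and 460 nm (blue) for
#' visualization and grayscale conversion.
#'
#' @param cube [spectral_cube()] whose wavelengths cover the visible range.
#' @return height x width x 3 array in R, G, B order.
#' @export
rgb_composite <- function(cube) {
  idx <- c(band_at(cube, 642), band_at(cube, 546), band_at(cube, 460))
  cube$data[, , idx, drop = FALSE]
}

#' Full segmentation of a scene cube
#'
#' Runs the rule mask, morphological opening, hole repair, component
#' extraction with the 250-1500 px area filter and grid labeling in sequence.
#'
#' @param cube reflectance [spectral_cube()].
#' @param min_area,max_area strict component area bounds.
#' @param rows,cols seed grid layout for labeling.
#' @return `list(mask =, components =, labels =)`.
#' @export
segment_scene <- function(cube, min_area = 250, max_area = 1500, rows = 6L, cols = 4L) {
  m <- rule_mask(cube)
  m <- morphological_open(m)
  m <- repair_holes(m)
  ext <- extract_components(m, min_area, max_area)
  ext$components <- grid_label(ext$components, rows = rows, cols = cols)
  list(mask = m, components = ext$components, labels = ext$labels)
}

#' Write a binary mask as a PNG file
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
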