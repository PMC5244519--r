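# Visual-field-sign segmentation: reversals in the progression of
# retinotopy are sign changes of the retinotopic Jacobian, so the field
# sign (sign of the cross product of the azimuth and elevation gradients)
# partitions cortex into mirror/non-mirror areas. Components are named by
# their position relative to V1 (the largest component), using a template
# of centroid offsets normalized by V1 size.

#' Gaussian blur of an image
#'
#' Separable Gaussian convolution with zero padding and kernel-weight
#' renormalization at the edges (so constant images stay constant).
#'
#' @param img Numeric matrix.
#' @param sigma_px Gaussian SD in pixels.
#' @param size Odd kernel support; default `2 * ceiling(3 * sigma) + 1`.
#' @return Blurred matrix of the same shape.
#' @export
gauss_blur <- function(img, sigma_px, size = NULL) {
  if (sigma_px <= 0) return(img)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma_px) + 1L
  stopifnot(size %% 2L == 1L)
  half <- (size - 1L) %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  # NA-aware normalized convolution: NAs (and edges) contribute zero weight
  conv1 <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- nrow(m)
    val <- m
    ok_in <- !is.na(val)
    val[!ok_in] <- 0
    acc <- matrix(0, nrow(m), ncol(m))
    wgt <- matrix(0, nrow(m), ncol(m))
    for (o in -half:half) {
      src <- seq_len(n) + o
      ok <- src >= 1L & src <= n
      acc[ok, ] <- acc[ok, ] + k[o + half + 1L] * val[src[ok], ]
      wgt[ok, ] <- wgt[ok, ] + k[o + half + 1L] * ok_in[src[ok], ]
    }
    out <- acc / wgt
    out[wgt == 0] <- NA
    if (along_rows) t(out) else out
  }
  conv1(conv1(img, FALSE), TRUE)
}

.shift_mat <- function(m, o_r, o_c) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(m[1][NA], h, w)
  rs <- max(1, 1 + o_r):min(h, h + o_r)
  cs <- max(1, 1 + o_c):min(w, w + o_c)
  out[rs - o_r, cs - o_c] <- m[rs, cs]
  out
}

# circular phase gradients of a complex field (radians / pixel); central
# differences with one-sided fallback where a neighbor is missing
.circ_gradients <- function(z) {
  one_axis <- function(fwd, bwd) {
    g <- Arg(fwd * Conj(bwd)) / 2
    only_f <- is.na(bwd) & !is.na(fwd) & !is.na(z)
    only_b <- is.na(fwd) & !is.na(bwd) & !is.na(z)
    g[only_f] <- Arg(fwd * Conj(z))[only_f]
    g[only_b] <- Arg(z * Conj(bwd))[only_b]
    g
  }
  list(dx = one_axis(.shift_mat(z, 0L, 1L), .shift_mat(z, 0L, -1L)),
       dy = one_axis(.shift_mat(z, 1L, 0L), .shift_mat(z, -1L, 0L)))
}

#' Visual field sign from a retinotopy pair
#'
#' Smooths the azimuth and elevation maps, then takes the sign of the
#' z-component of the cross product of their spatial gradients
#' (`dA/dx * dE/dy - dA/dy * dE/dx`). Cross-product magnitudes at or below
#' `noise_floor` map to 0.
#'
#' @param retino A [retinotopy_from_phases()] result (or any list with
#'   `azimuth_deg` and `elevation_deg` matrices).
#' @param smooth_sigma_px Gaussian smoothing SD, pixels (default 2).
#' @param noise_floor Absolute Jacobian magnitude below which the sign is
#'   set to 0 (default effectively zero).
#' @param mask Optional logical matrix restricting the computation to
#'   responsive cortex: phase outside it is unreliable, and the
#'   NA-aware smoothing prevents it from polluting in-mask gradients.
#' @return An object of class `field_sign_map` with matrix `sign` in
#'   `{-1, 0, 1}` (0 outside the mask and below the noise floor).
#' @export
field_sign <- function(retino, smooth_sigma_px = 2, noise_floor = 1e-9,
                       mask = NULL) {
  # Degrees at the two ends of a sweep are circularly adjacent (they come
  # from a periodic phase), so each map is lifted onto the unit circle,
  # smoothed as a complex field, and differentiated circularly; the
  # Jacobian sign is invariant to the (positive) rescaling.
  to_circle <- function(deg, range) {
    if (is.null(range)) range <- range(deg, na.rm = TRUE)
    span <- range[2] - range[1]
    if (span <= 0) return(matrix(complex(real = 1), nrow(deg), ncol(deg)))
    th <- (deg - range[1]) / span * 2 * pi
    exp(1i * th)
  }
  azi <- retino$azimuth_deg
  ele <- retino$elevation_deg
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(azi)))
    azi[!mask] <- NA
    ele[!mask] <- NA
  }
  za <- to_circle(azi, retino$azimuth_range_deg %||% NULL)
  ze <- to_circle(ele, retino$elevation_range_deg %||% NULL)
  smooth_c <- function(z) {
    complex(real = gauss_blur(Re(z), smooth_sigma_px),
            imaginary = gauss_blur(Im(z), smooth_sigma_px)) |>
      matrix(nrow(z), ncol(z))
  }
  ga <- .circ_gradients(smooth_c(za))
  ge <- .circ_gradients(smooth_c(ze))
  cross <- ga$dx * ge$dy - ga$dy * ge$dx
  s <- sign(cross)
  s[is.na(s)] <- 0
  s[abs(cross) <= noise_floor & !is.na(cross)] <- 0
  if (!is.null(mask)) s[!mask] <- 0
  if (all(s == 0)) message("field sign is zero everywhere (constant maps?)")
  structure(list(sign = s, smooth_sigma_px = smooth_sigma_px),
            class = "field_sign_map")
}

# connected components of equal nonzero value, 4-connectivity (flood fill)
.label_components <- function(codes) {
  h <- nrow(codes); w <- ncol(codes)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  queue <- integer(h * w)
  for (start in which(codes != 0 & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    v <- codes[start]
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    lab[start] <- nxt
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (nb in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                   if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (lab[nb] == 0L && codes[nb] == v) {
          lab[nb] <- nxt
          qt <- qt + 1L
          queue[qt] <- nb
        }
      }
    }
  }
  lab
}

# HVA centroid offsets from the V1 centroid, in units of sqrt(V1 pixel
# area); derived from the default sheet layout. x = lateral, y = anterior
# (matrix row direction).
.DEFAULT_NAMING_TEMPLATE <- rbind(
  LM   = c(0.673, -0.279),
  LI   = c(1.084, -0.279),
  AL   = c(0.681,  0.361),
  RL   = c(0.099,  0.747),
  AMPM = c(-0.443, 0.796))

#' Segment named visual areas from a field sign map
#'
#' Connected components of constant nonzero field sign inside the
#' responsive mask, minimum-size filtered. The largest component is V1;
#' the remaining components are named by the position of their centroid
#' relative to V1 (offset normalized by sqrt(V1 area)), matched greedily
#' to a template of expected HVA positions (nearest template centroid,
#' larger components first). Unassignable components become background
#' with a warning.
#'
#' @param fs A [field_sign()] map.
#' @param responsive_mask Logical matrix, same shape (e.g. from
#'   [responsive_mask()]).
#' @param min_size_px Minimum component size in binned pixels
#'   (default 100).
#' @param open_px Morphological opening radius applied to each sign class
#'   before labeling; cuts thin same-sign bridges through the mask halo
#'   between areas (default 1).
#' @param grow_px After naming, regrow each component within the mask by
#'   this many pixels (multi-source dilation, fronts stop where they
#'   meet); recovers the border band consumed by opening and by sign
#'   mixing at area borders (default `open_px + 2`).
#' @param template Naming template: matrix with rownames = area names and
#'   two columns (normalized x, y offsets from the V1 centroid).
#' @return An object of class `area_label_map`: `labels` (`H x W`
#'   integer) and `names` (character vector indexed by label).
#' @export
segment_areas <- function(fs, responsive_mask, min_size_px = 100,
                          open_px = 1, grow_px = open_px + 2,
                          template = .DEFAULT_NAMING_TEMPLATE) {
  stopifnot(identical(dim(fs$sign), dim(responsive_mask)))
  erode1 <- function(m) {
    m & .shift_logical(m, 1L, 0L) & .shift_logical(m, -1L, 0L) &
      .shift_logical(m, 0L, 1L) & .shift_logical(m, 0L, -1L)
  }
  codes0 <- fs$sign
  codes0[!responsive_mask] <- 0
  codes <- codes0
  for (s in c(-1, 1)) {
    ms <- codes == s
    for (i in seq_len(open_px)) ms <- erode1(ms)
    codes[codes == s & !ms] <- 0
  }
  comp <- .label_components(codes)
  # complete the opening: dilate each component back onto same-sign
  # pixels it was eroded from (bridges stay cut; area cores regain their
  # rim before the size filter sees them)
  n_comp <- max(comp)
  if (n_comp > 0) {
    sign_of <- integer(n_comp)
    for (l in seq_len(n_comp)) sign_of[l] <- codes[which(comp == l)[1]]
    for (i in seq_len(open_px)) {
      cand <- codes0 != 0 & comp == 0L
      if (!any(cand)) break
      new_comp <- comp
      for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        nb <- .shift_int(comp, sh[1], sh[2])
        take <- cand & new_comp == 0L & nb > 0L
        take[take] <- codes0[take] == sign_of[nb[take]]
        new_comp[take] <- nb[take]
      }
      comp <- new_comp
    }
  }
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_size_px)
  if (!length(keep)) {
    stop("no field-sign component reaches the minimum size (",
         min_size_px, " px)")
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  h <- nrow(comp)
  centroid <- function(ids) {
    idx <- which(comp %in% ids)
    c(x = mean(((idx - 1L) %/% h) + 1L), y = mean(((idx - 1L) %% h) + 1L))
  }
  v1_id <- keep[1L]
  v1_c <- centroid(v1_id)
  v1_scale <- sqrt(sizes[v1_id])
  assigned <- c(V1 = v1_id)
  avail <- rownames(template)
  for (cid in keep[-1L]) {
    if (!length(avail)) {
      warning("more components than template areas; extra component -> ",
              "background")
      next
    }
    cc <- centroid(cid)
    off <- (cc - v1_c) / v1_scale
    d2 <- (template[avail, 1] - off["x"])^2 +
          (template[avail, 2] - off["y"])^2
    nm <- avail[which.min(d2)]
    assigned[nm] <- cid
    avail <- setdiff(avail, nm)
  }
  labels <- matrix(0L, nrow(comp), ncol(comp))
  out_names <- character(length(assigned))
  order_names <- intersect(c("V1", rownames(template)), names(assigned))
  for (i in seq_along(order_names)) {
    nm <- order_names[i]
    labels[comp == assigned[[nm]]] <- i
    out_names[i] <- nm
  }
  dropped <- setdiff(which(sizes >= min_size_px), unlist(assigned))
  if (length(dropped)) {
    warning(length(dropped), " component(s) left unassigned -> background")
  }
  # bounded regrowth within the mask: simultaneous 4-neighbor dilation of
  # all named components; fronts stop where they meet (first writer, in a
  # fixed neighbor order, wins -> deterministic)
  for (i in seq_len(grow_px)) {
    cand <- responsive_mask & labels == 0L
    if (!any(cand)) break
    new_lab <- labels
    for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nb <- .shift_int(labels, sh[1], sh[2])
      take <- cand & new_lab == 0L & nb > 0L
      new_lab[take] <- nb[take]
    }
    labels <- new_lab
  }
  structure(list(labels = labels, names = out_names[seq_along(order_names)]),
            class = "area_label_map")
}

.shift_logical <- function(m, o_r, o_c) {
  out <- .shift_mat(m * 1L, o_r, o_c)
  out[is.na(out)] <- 0L
  out > 0L
}

.shift_int <- function(m, o_r, o_c) {
  out <- .shift_mat(m, o_r, o_c)
  out[is.na(out)] <- 0L
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b Logical matrices of equal shape.
#' @return `2|a & b| / (|a| + |b|)` (1 when both are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Per-area Dice between a segmentation and ground-truth labels
#'
#' @param seg An [segment_areas()] result.
#' @param truth_labels Integer label matrix with a `names_by_label`
#'   attribute (e.g. [bin_label_image()] of a sheet's label image).
#' @return Named numeric Dice per ground-truth area (0 where an area was
#'   not recovered).
#' @export
segmentation_dice <- function(seg, truth_labels) {
  truth_names <- attr(truth_labels, "names_by_label")
  out <- stats::setNames(numeric(length(truth_names)), truth_names)
  for (i in seq_along(truth_names)) {
    nm <- truth_names[i]
    tr <- truth_labels == i
    li <- match(nm, seg$names)
    rec <- if (is.na(li)) matrix(FALSE, nrow(tr), ncol(tr))
           else seg$labels == li
    out[nm] <- dice_coefficient(tr, rec)
  }
  out
}

#' Export an area label map as TIFF + JSON name table
#'
#' @param map An `area_label_map`.
#' @param path Output TIFF path; the name table is written next to it as
#'   `.json`.
#' @export
export_labels <- function(map, path) {
  tiff_write(matrix(as.numeric(map$labels), nrow(map$labels)), path,
             sample_format = "uint16")
  jsonlite::write_json(as.list(stats::setNames(map$names,
                                               seq_along(map$names))),
                       .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Import an area label map (e.g. manually drawn ROIs)
#'
#' Reads a label TIFF and its JSON name table, validates names, and
#' optionally merges separate AM and PM labels into a single AMPM label
#' (the two areas are combined for analysis because their mutual border is
#' not reliably resolved).
#'
#' @param path Label TIFF path (name table next to it as `.json`).
#' @param merge_ampm Merge labels named `AM` and `PM` into `AMPM`
#'   (default TRUE).
#' @return An `area_label_map`.
#' @export
import_labels <- function(path, merge_ampm = TRUE) {
  tif <- tiff_read(path)
  lab <- tif$data[, , 1]
  if (any(lab != round(lab))) stop("label image has non-integer pixels")
  tab <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  ids <- as.integer(names(tab))
  nms <- as.character(unlist(tab))
  if (anyDuplicated(nms)) stop("duplicate area names in name table")
  labels <- matrix(0L, nrow(lab), ncol(lab))
  if (merge_ampm && all(c("AM", "PM") %in% nms)) {
    nms[nms == "AM"] <- "AMPM"
    keep <- nms != "PM"
    # PM pixels get AM's (now AMPM's) label id
    pm_id <- ids[which(unlist(tab) == "PM")]
    am_id <- ids[which(unlist(tab) == "AM")]
    lab[lab == pm_id] <- am_id
    ids <- ids[keep]; nms <- nms[keep]
  }
  out_names <- character(length(ids))
  for (i in seq_along(ids)) {
    labels[lab == ids[i]] <- i
    out_names[i] <- nms[i]
  }
  if (!"V1" %in% out_names) {
    stop("name table has no V1 label: V1 normalization impossible")
  }
  structure(list(labels = labels, names = out_names),
            class = "area_label_map")
}
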