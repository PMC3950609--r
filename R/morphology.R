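#' @useDynLib rgcsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft lm coef fitted approx median quantile sd setNames qnorm pnorm runif
#' @importFrom utils head tail
NULL

REGIONS <- c("soma", "dendrite", "initial_segment", "narrow_segment", "distal_axon")
AXONAL_REGIONS <- c("initial_segment", "narrow_segment", "distal_axon")

#' Standard axon geometry
#'
#' Dimensions of the four-region axon attached to every cell: an initial
#' segment stemming from the soma, a thin narrow segment, and a long distal
#' axon, with a sodium-channel band (SOCB) overlay spanning the distal part of
#' the initial segment and the proximal part of the narrow segment. The SOCB
#' starts 30 um from the soma along the axon and extends for 40 um.
#'
#' @param initial_segment_length um, default 40
#' @param narrow_length um, default 90
#' @param narrow_diameter um, default 0.4
#' @param distal_length um, default 5340
#' @param distal_diameter um, default 1 (the initial segment shares it)
#' @param socb_start um from the soma, default 30
#' @param socb_length um, default 40
#' @return a list of class `rgc_axon_spec`
#' @export
axon_spec <- function(initial_segment_length = 40, narrow_length = 90,
                      narrow_diameter = 0.4, distal_length = 5340,
                      distal_diameter = 1, socb_start = 30, socb_length = 40) {
  spec <- list(
    initial_segment_length = initial_segment_length,
    initial_segment_diameter = distal_diameter,
    narrow_length = narrow_length, narrow_diameter = narrow_diameter,
    distal_length = distal_length, distal_diameter = distal_diameter,
    socb_start = socb_start, socb_length = socb_length
  )
  stopifnot(all(unlist(spec) > 0),
            socb_start + socb_length <= initial_segment_length + narrow_length)
  class(spec) <- "rgc_axon_spec"
  spec
}

new_morphology <- function(df, spec = axon_spec()) {
  rownames(df) <- NULL
  structure(df, class = c("rgc_morphology", "data.frame"), axon_spec = spec)
}

get_axon_spec <- function(morph) {
  spec <- attr(morph, "axon_spec")
  if (is.null(spec)) axon_spec() else spec
}

#' Validate a morphology's structural invariants
#'
#' Checks the single-soma-root contract, tree connectivity (every non-root
#' compartment has an existing, earlier parent), positive geometry, and the
#' consistency of SOCB flags with the arc-distance window.
#'
#' @param morph an `rgc_morphology`
#' @return the morphology, invisibly; errors on violation
#' @export
validate_morphology <- function(morph) {
  df <- as.data.frame(morph)
  if (nrow(df) == 0) stop("empty morphology")
  roots <- which(is.na(df$parent_id))
  if (length(roots) != 1) stop("morphology must have exactly one root")
  if (df$region[roots] != "soma") stop("root compartment must be soma")
  if (roots != 1) stop("root must be compartment 1")
  if (!all(df$id == seq_len(nrow(df)))) stop("ids must be 1..n")
  nr <- df$parent_id[-roots]
  if (any(!nr %in% df$id)) stop("parent_id refers to a missing compartment")
  if (any(nr >= df$id[-roots])) stop("parents must precede children")
  if (any(df$length <= 0) || any(df$diameter <= 0))
    stop("lengths and diameters must be strictly positive")
  if (!all(df$region %in% REGIONS)) stop("unknown region label")
  ax <- df$region %in% AXONAL_REGIONS
  spec <- get_axon_spec(morph)
  expected <- ax & !is.na(df$arc_from_soma) &
    df$arc_from_soma >= spec$socb_start &
    df$arc_from_soma < spec$socb_start + spec$socb_length
  if (!identical(as.logical(df$in_socb), as.logical(expected)))
    stop("in_socb flags inconsistent with arc distance window")
  invisible(morph)
}

#' Read a neuron reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius, parent;
#' `#` comments) into a compartmental morphology. Each non-soma point becomes a
#' cylinder whose length is the Euclidean distance to its parent point and
#' whose diameter is twice the point radius. All soma points are collapsed to a
#' single equivalent-lateral-area cylinder with aspect ratio L = d (a lone
#' soma point of radius r maps to d = L = 2r, preserving the sphere area
#' 4*pi*r^2). Axon points are assigned to the initial/narrow/distal regions by
#' path distance from the soma; unknown type codes are treated as dendrite.
#'
#' @param path SWC file path
#' @param spec an [axon_spec()] used for axonal region boundaries
#' @return an `rgc_morphology`
#' @export
read_swc <- function(path, spec = axon_spec()) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7)
  if (length(bad))
    stop(sprintf("malformed SWC line %d: expected 7 columns", lineno[bad[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  nn <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(nn))
    stop(sprintf("malformed SWC line %d: non-numeric field", lineno[nn[1]]))
  pts <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                    z = m[, 5], radius = m[, 6], parent = m[, 7])
  if (any(pts$radius <= 0)) stop("SWC point with non-positive radius")
  if (anyDuplicated(pts$id)) stop("duplicate SWC point ids")
  roots <- which(pts$parent == -1)
  if (length(roots) != 1) stop("SWC must have exactly one root point")
  if (pts$type[roots] != 1) stop("SWC root point must be a soma point")
  idx <- match(pts$parent, pts$id)
  orphan <- which(pts$parent != -1 & is.na(idx))
  if (length(orphan))
    stop(sprintf("SWC point %d has a missing parent %d",
                 pts$id[orphan[1]], pts$parent[orphan[1]]))
  soma_rows <- pts$type == 1
  if (!any(soma_rows)) stop("SWC contains no soma point")

  # collapse soma points into one equal-lateral-area cylinder with L = d
  if (sum(soma_rows) == 1) {
    soma_area <- 4 * pi * pts$radius[soma_rows]^2
  } else {
    sr <- which(soma_rows)
    seg <- sr[!is.na(idx[sr]) & idx[sr] %in% which(soma_rows)]
    dist <- sqrt((pts$x[seg] - pts$x[idx[seg]])^2 +
                 (pts$y[seg] - pts$y[idx[seg]])^2 +
                 (pts$z[seg] - pts$z[idx[seg]])^2)
    soma_area <- sum(pi * 2 * pts$radius[seg] * dist)
    if (soma_area <= 0) soma_area <- 4 * pi * max(pts$radius[soma_rows])^2
  }
  soma_d <- sqrt(soma_area / pi)

  other <- which(!soma_rows)
  # map every point to its compartment id: soma points -> 1
  comp_of <- integer(nrow(pts))
  comp_of[soma_rows] <- 1L
  comp_of[other] <- seq_along(other) + 1L
  len <- sqrt((pts$x[other] - pts$x[idx[other]])^2 +
              (pts$y[other] - pts$y[idx[other]])^2 +
              (pts$z[other] - pts$z[idx[other]])^2)
  if (any(len <= 0))
    stop("zero-length SWC segment (point coincides with its parent)")
  df <- data.frame(
    id = comp_of[other],
    parent_id = comp_of[idx[other]],
    region = if (length(other)) ifelse(pts$type[other] == 2, "initial_segment",
                                       "dendrite") else character(0),
    length = len,
    diameter = 2 * pts$radius[other],
    arc_from_soma = rep(NA_real_, length(other)),
    in_socb = rep(FALSE, length(other))
  )
  soma <- data.frame(id = 1L, parent_id = NA_integer_, region = "soma",
                     length = soma_d, diameter = soma_d,
                     arc_from_soma = NA_real_, in_socb = FALSE)
  df <- rbind(soma, df[order(df$id), ])
  # children may precede parents in pathological SWC ordering; re-sort
  df <- toposort_morphology(df)
  df <- recompute_axonal_regions(df, spec)
  morph <- new_morphology(df, spec)
  validate_morphology(morph)
  morph
}

# re-index compartments so every parent precedes its children
toposort_morphology <- function(df) {
  n <- nrow(df)
  order_new <- integer(n)
  pos <- 1L
  queue <- which(is.na(df$parent_id))
  children <- split(seq_len(n), factor(df$parent_id, levels = df$id))
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    order_new[pos] <- i
    pos <- pos + 1L
    kids <- children[[as.character(df$id[i])]]
    if (length(kids)) queue <- c(queue, kids)
  }
  if (pos != n + 1L) stop("morphology tree is not connected")
  out <- df[order_new, ]
  remap <- setNames(seq_len(n), out$id)
  out$id <- seq_len(n)
  out$parent_id <- ifelse(is.na(out$parent_id), NA_integer_,
                          remap[as.character(out$parent_id)])
  rownames(out) <- NULL
  out
}

# assign axonal regions and SOCB flags from midpoint path distance
recompute_axonal_regions <- function(df, spec) {
  ax <- df$region %in% AXONAL_REGIONS
  df$arc_from_soma <- NA_real_
  df$in_socb <- FALSE
  if (!any(ax)) return(df)
  start <- numeric(nrow(df))
  for (i in which(ax)) {
    p <- df$parent_id[i]
    start[i] <- if (!is.na(p) && df$region[p] %in% AXONAL_REGIONS)
      start[p] + df$length[p] else 0
    mid <- start[i] + df$length[i] / 2
    df$arc_from_soma[i] <- mid
    b1 <- spec$initial_segment_length
    b2 <- b1 + spec$narrow_length
    df$region[i] <- if (mid < b1) "initial_segment"
                    else if (mid < b2) "narrow_segment" else "distal_axon"
    df$in_socb[i] <- mid >= spec$socb_start &&
      mid < spec$socb_start + spec$socb_length
  }
  df
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()] up to coordinate layout: compartments are placed on
#' a deterministic synthetic 3D embedding (directions only carry lengths; the
#' electrical model is purely topological). The soma cylinder is written as a
#' single soma point with the sphere-equivalent radius `sqrt(L*d)/2`, so the
#' read-back morphology preserves compartment count and every surface area.
#'
#' @param morph an `rgc_morphology`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_swc <- function(morph, path) {
  validate_morphology(morph)
  df <- as.data.frame(morph)
  n <- nrow(df)
  # golden-angle direction sequence: distinct, deterministic unit vectors
  dir_for <- function(k) {
    ga <- pi * (3 - sqrt(5))
    zc <- 1 - 2 * ((k %% 97) + 0.5) / 97
    r <- sqrt(max(0, 1 - zc^2))
    c(r * cos(ga * k), r * sin(ga * k), zc)
  }
  end <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    p <- df$parent_id[i]
    end[i, ] <- end[p, ] + dir_for(i) * df$length[i]
  }
  type <- ifelse(df$region == "soma", 1L,
                 ifelse(df$region %in% AXONAL_REGIONS, 2L, 3L))
  radius <- df$diameter / 2
  radius[1] <- sqrt(df$length[1] * df$diameter[1]) / 2
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   df$id, type, end[, 1], end[, 2], end[, 3], radius,
                   ifelse(is.na(df$parent_id), -1L, df$parent_id))
  writeLines(c("# SWC written by rgcsim", lines), path)
  invisible(path)
}

#' Attach the standardized four-region axon
#'
#' Removes any pre-existing axonal compartments and attaches the standard
#' chain initial segment -> narrow segment -> distal axon at the soma.
#' Compartment boundaries are pinned at the SOCB limits (30 and 70 um) and the
#' region limits (40 and 130 um) so the SOCB is exactly representable under
#' any further discretization; SOCB flags are set on compartments whose
#' midpoint arc distance falls in [30, 70) um.
#'
#' @param morph an `rgc_morphology`
#' @param spec an [axon_spec()]
#' @return the morphology with the standard axon
#' @export
attach_standard_axon <- function(morph, spec = axon_spec()) {
  df <- as.data.frame(morph)
  if (nrow(df) == 0 || df$region[1] != "soma" || !is.na(df$parent_id[1]))
    stop("morphology must have a soma root")
  keep <- !(df$region %in% AXONAL_REGIONS)
  df <- df[keep, ]
  df <- toposort_morphology(df)

  b_init <- spec$initial_segment_length
  b_socb0 <- spec$socb_start
  b_socb1 <- spec$socb_start + spec$socb_length
  stopifnot(b_socb0 < b_init, b_socb1 > b_init,
            b_socb1 < b_init + spec$narrow_length)
  pieces <- data.frame(
    region = c("initial_segment", "initial_segment",
               "narrow_segment", "narrow_segment", "distal_axon"),
    length = c(b_socb0, b_init - b_socb0,
               b_socb1 - b_init, b_init + spec$narrow_length - b_socb1,
               spec$distal_length),
    diameter = c(spec$initial_segment_diameter, spec$initial_segment_diameter,
                 spec$narrow_diameter, spec$narrow_diameter,
                 spec$distal_diameter)
  )
  n0 <- nrow(df)
  ids <- n0 + seq_len(nrow(pieces))
  ax <- data.frame(id = ids,
                   parent_id = c(1L, head(ids, -1)),
                   region = pieces$region, length = pieces$length,
                   diameter = pieces$diameter,
                   arc_from_soma = NA_real_, in_socb = FALSE)
  out <- rbind(df, ax)
  out <- recompute_axonal_regions(out, spec)
  morph <- new_morphology(out, spec)
  validate_morphology(morph)
  morph
}

#' Split long compartments for the cable solver
#'
#' Splits every compartment longer than `max_segment_length` into equal
#' sub-cylinders of the same diameter. Region labels and SOCB flags are
#' recomputed from midpoint arc distance; total lateral area is conserved
#' exactly.
#'
#' @param morph an `rgc_morphology`
#' @param max_segment_length um, > 0
#' @return the discretized morphology
#' @export
discretize <- function(morph, max_segment_length) {
  stopifnot(max_segment_length > 0)
  df <- as.data.frame(morph)
  spec <- get_axon_spec(morph)
  rows <- vector("list", nrow(df))
  new_id_of <- integer(nrow(df)) # id of the last piece of each old compartment
  next_id <- 0L
  for (i in seq_len(nrow(df))) {
    k <- max(1L, ceiling(df$length[i] / max_segment_length))
    piece_len <- df$length[i] / k
    ids <- next_id + seq_len(k)
    parent0 <- if (is.na(df$parent_id[i])) NA_integer_
               else new_id_of[df$parent_id[i]]
    rows[[i]] <- data.frame(
      id = ids,
      parent_id = c(parent0, head(ids, -1)),
      region = df$region[i], length = piece_len, diameter = df$diameter[i],
      arc_from_soma = NA_real_, in_socb = FALSE
    )
    new_id_of[i] <- ids[k]
    next_id <- next_id + k
  }
  out <- do.call(rbind, rows)
  out <- recompute_axonal_regions(out, spec)
  morph2 <- new_morphology(out, spec)
  validate_morphology(morph2)
  morph2
}

lateral_area <- function(df) pi * df$diameter * df$length

#' Morphometric statistics of a cell
#'
#' Computes the standard cell-level statistics: lateral surface areas by
#' region (end faces omitted; the total excludes the axon), the
#' dendrite-to-total and soma-to-total area ratios, dendritic tip and
#' bifurcation counts, and mean dendritic compartment length/diameter. The
#' axon diameter is reported as the length-weighted mean over axonal
#' compartments.
#'
#' @param morph an `rgc_morphology`
#' @return a list of class `rgc_morphometry`
#' @export
morphometry <- function(morph) {
  df <- as.data.frame(morph)
  area <- lateral_area(df)
  soma <- df$region == "soma"
  dend <- df$region == "dendrite"
  ax <- df$region %in% AXONAL_REGIONS
  s_soma <- sum(area[soma])
  s_dend <- sum(area[dend])
  s_axon <- sum(area[ax])
  s_total <- s_soma + s_dend
  n_dend_children <- tabulate(df$parent_id[dend], nbins = nrow(df))
  tips <- dend & n_dend_children == 0
  bif <- dend & n_dend_children >= 2
  out <- list(
    s_total = s_total, s_soma = s_soma, s_axon = s_axon, s_dendrite = s_dend,
    d_axon = if (any(ax)) sum(df$diameter[ax] * df$length[ax]) /
      sum(df$length[ax]) else NA_real_,
    d_dendrite_mean = if (any(dend)) mean(df$diameter[dend]) else NA_real_,
    r_dend_total = s_dend / s_total,
    r_soma_total = s_soma / s_total,
    n_tips = sum(tips),
    n_bifurcations = sum(bif),
    mean_dendritic_compartment_length =
      if (any(dend)) mean(df$length[dend]) else NA_real_
  )
  class(out) <- "rgc_morphometry"
  out
}

#' @export
print.rgc_morphometry <- function(x, ...) {
  cat(sprintf(
    paste0("Morphometry: S_total %.1f um^2 (soma %.1f, dendrite %.1f), ",
           "S_axon %.1f um^2\n  R_dend,total %.3f  R_soma,total %.3f  ",
           "tips %d  bifurcations %d\n"),
    x$s_total, x$s_soma, x$s_dendrite, x$s_axon,
    x$r_dend_total, x$r_soma_total, x$n_tips, x$n_bifurcations))
  invisible(x)
}

#' Shrink parts of a morphology
#'
#' Applies a multiplicative reduction to dendritic diameters, dendritic
#' lengths, or the soma (both its diameter and length), leaving the axon and
#' all per-area channel densities untouched.
#'
#' @param morph an `rgc_morphology`
#' @param target one of `"dendrite_diameter"`, `"dendrite_length"`, `"soma"`
#' @param factor in (0, 1]
#' @return the scaled morphology
#' @export
scale_morphology <- function(morph,
                             target = c("dendrite_diameter", "dendrite_length",
                                        "soma"),
                             factor) {
  target <- match.arg(target)
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]")
  df <- as.data.frame(morph)
  dend <- df$region == "dendrite"
  soma <- df$region == "soma"
  if (target == "dendrite_diameter") df$diameter[dend] <- df$diameter[dend] * factor
  if (target == "dendrite_length") df$length[dend] <- df$length[dend] * factor
  if (target == "soma") {
    df$diameter[soma] <- df$diameter[soma] * factor
    df$length[soma] <- df$length[soma] * factor
  }
  morph2 <- new_morphology(df, get_axon_spec(morph))
  validate_morphology(morph2)
  morph2
}
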