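#' Histogram of a cell-table parameter
#'
#' @param table cell table (data.frame).
#' @param parameter column name.
#' @param bins number of bins (>= 1).
#' @param transform `"linear"` or `"log10"`.
#' @return list with `counts` (summing to the number of finite values),
#'   `edges`, `mids`, `parameter`, `transform`.
#' @export
make_histogram <- function(table, parameter, bins = 256,
                           transform = c("linear", "log10")) {
  transform <- match.arg(transform)
  if (!parameter %in% names(table))
    .stop2("parameter_error", "no column '%s'", parameter)
  if (bins < 1) .stop2("parameter_error", "bins must be >= 1")
  v <- table[[parameter]]
  v <- v[is.finite(v)]
  if (transform == "log10") {
    npos <- sum(v <= 0)
    if (npos > 0)
      .stop2("transform_error",
             "log10 transform with %d non-positive value(s)", npos)
    v <- log10(v)
  }
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), bins),
                     nbins = bins)
  list(counts = counts, edges = edges, mids = (edges[-1] + edges[-(bins + 1)]) / 2,
       parameter = parameter, transform = transform)
}

# ---- gates ------------------------------------------------------------------

#' Gate constructors
#'
#' Gates select subpopulations in measurement space: `gate_range()` an
#' interval on one parameter, `gate_rect()` an axis-aligned rectangle on
#' two, `gate_polygon()` a simple polygon, `gate_boolean()` an AND / OR /
#' NOT combination of previously defined gates. Each geometric gate can
#' apply a per-axis `log10` transform before testing membership. Interval
#' and polygon boundaries are inclusive.
#'
#' @param name gate name (unique within a gate set).
#' @param axis,axes parameter column name(s).
#' @param min,max interval limits.
#' @param xlim,ylim rectangle limits (length 2 each).
#' @param vertices polygon vertex matrix (n x 2, columns = axes).
#' @param transform,transforms `"linear"` or `"log10"` per axis.
#' @param op `"AND"`, `"OR"` or `"NOT"`.
#' @param operands character vector of operand gate names (1 for NOT).
#' @param parent optional parent gate name for percent-of-parent statistics.
#' @return a `gate` object.
#' @name gates
NULL

#' @rdname gates
#' @export
gate_range <- function(name, axis, min, max, transform = "linear",
                       parent = NULL) {
  structure(list(name = name, kind = "range1D", axes = axis,
                 geometry = c(min = min, max = max),
                 transforms = transform, parent = parent), class = "gate")
}

#' @rdname gates
#' @export
gate_rect <- function(name, axes, xlim, ylim,
                      transforms = c("linear", "linear"), parent = NULL) {
  structure(list(name = name, kind = "rectangle", axes = axes,
                 geometry = list(xlim = sort(xlim), ylim = sort(ylim)),
                 transforms = transforms, parent = parent), class = "gate")
}

#' @rdname gates
#' @export
gate_polygon <- function(name, axes, vertices,
                         transforms = c("linear", "linear"), parent = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    .stop2("validation_error", "polygon gate needs >= 3 vertices")
  if (.polygon_self_intersects(vertices))
    .stop2("validation_error", "polygon gate '%s' is self-intersecting", name)
  structure(list(name = name, kind = "polygon", axes = axes,
                 geometry = vertices, transforms = transforms,
                 parent = parent), class = "gate")
}

#' @rdname gates
#' @export
gate_boolean <- function(name, op = c("AND", "OR", "NOT"), operands,
                         parent = NULL) {
  op <- match.arg(op)
  if (op == "NOT" && length(operands) != 1L)
    .stop2("validation_error", "NOT takes exactly one operand")
  structure(list(name = name, kind = "boolean", op = op,
                 operands = operands, parent = parent), class = "gate")
}

.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2))
    for (j in (i + 2):n)
      if (!(i == 1 && j == n) && inter(seg[i, ], seg[j, ])) return(TRUE)
  FALSE
}

.axis_values <- function(table, axis, transform) {
  if (!axis %in% names(table)) .stop2("configuration_error", "no column '%s'", axis)
  v <- table[[axis]]
  if (identical(transform, "log10")) {
    v <- ifelse(v > 0, suppressWarnings(log10(v)), NA_real_)
  }
  v
}

.gate_membership <- function(table, g) {
  if (g$kind == "range1D") {
    v <- .axis_values(table, g$axes[1], g$transforms[1])
    !is.na(v) & v >= g$geometry["min"] & v <= g$geometry["max"]
  } else if (g$kind == "rectangle") {
    x <- .axis_values(table, g$axes[1], g$transforms[1])
    y <- .axis_values(table, g$axes[2], g$transforms[2])
    !is.na(x) & !is.na(y) &
      x >= g$geometry$xlim[1] & x <= g$geometry$xlim[2] &
      y >= g$geometry$ylim[1] & y <= g$geometry$ylim[2]
  } else if (g$kind == "polygon") {
    x <- .axis_values(table, g$axes[1], g$transforms[1])
    y <- .axis_values(table, g$axes[2], g$transforms[2])
    ok <- !is.na(x) & !is.na(y)
    m <- logical(length(x))
    if (any(ok))
      m[ok] <- pracma::inpolygon(x[ok], y[ok], g$geometry[, 1], g$geometry[, 2],
                                 boundary = TRUE)
    m
  } else .stop2("configuration_error", "unknown gate kind '%s'", g$kind)
}

#' Evaluate gates and compute population statistics
#'
#' Geometric gates are evaluated first, boolean gates afterwards in
#' dependency order (cycles are rejected). Statistics per gate: event
#' count, percent of all events, percent of the parent gate (100 if no
#' parent), and the mean of each requested parameter over members.
#'
#' @param table cell table.
#' @param gates list of `gate` objects.
#' @param stat_parameters numeric columns to average per gate (default: all
#'   numeric columns).
#' @return list with `membership` (logical matrix, one column per gate) and
#'   `stats` (data.frame of class `population_stats`).
#' @export
apply_gates <- function(table, gates, stat_parameters = NULL) {
  if (inherits(gates, "gate")) gates <- list(gates)
  nms <- vapply(gates, `[[`, "", "name")
  if (anyDuplicated(nms)) .stop2("configuration_error", "duplicate gate names")
  names(gates) <- nms
  n <- nrow(table)
  memb <- matrix(FALSE, n, length(gates), dimnames = list(NULL, nms))
  isbool <- vapply(gates, function(g) g$kind == "boolean", TRUE)
  for (g in gates[!isbool]) memb[, g$name] <- .gate_membership(table, g)
  # resolve boolean gates by repeated passes (detects cycles / dangling refs)
  todo <- nms[isbool]
  done <- nms[!isbool]
  while (length(todo)) {
    ready <- vapply(gates[todo], function(g) all(g$operands %in% done), TRUE)
    if (!any(ready)) {
      missing <- setdiff(unlist(lapply(gates[todo], `[[`, "operands")),
                         c(done, todo))
      if (length(missing))
        .stop2("configuration_error", "unresolvable gate reference(s): %s",
               paste(missing, collapse = ", "))
      .stop2("configuration_error", "boolean gate cycle involving: %s",
             paste(todo, collapse = ", "))
    }
    for (nm in todo[ready]) {
      g <- gates[[nm]]
      m <- memb[, g$operands, drop = FALSE]
      memb[, nm] <- switch(g$op,
                           AND = rowSums(m) == ncol(m),
                           OR = rowSums(m) > 0,
                           NOT = !m[, 1])
      done <- c(done, nm)
    }
    todo <- setdiff(todo, done)
  }
  if (is.null(stat_parameters))
    stat_parameters <- names(table)[vapply(table, is.numeric, TRUE)]
  stats <- do.call(rbind, lapply(nms, function(nm) {
    g <- gates[[nm]]
    sel <- memb[, nm]
    parent_n <- if (!is.null(g$parent) && g$parent %in% nms)
      sum(memb[, g$parent]) else n
    row <- data.frame(gate = nm, count = sum(sel),
                      pct_total = if (n > 0) 100 * sum(sel) / n else 0,
                      pct_parent = if (parent_n > 0) 100 * sum(sel) / parent_n else 0)
    for (p in stat_parameters)
      row[[paste0("mean_", p)]] <- if (any(sel)) mean(table[[p]][sel]) else NA_real_
    row
  }))
  class(stats) <- c("population_stats", "data.frame")
  list(membership = memb, stats = stats)
}

# ---- cell-cycle classification ---------------------------------------------

#' Cell-cycle classifier configuration
#'
#' The classifier works on DNA content (integrated DNA-stain intensity per
#' cell). The G1 peak position P is located as the lowest strong mode of a
#' kernel-smoothed DNA-content distribution; G1 is the window
#' `[g_lo, g_hi] * P` and G2 the window `[2 g_lo, 2 g_hi] * P`. In EdU mode
#' S-phase is called first from the EdU channel; in DNA-only mode S is
#' everything between the windows. Mitosis is overlaid on G2-window cells
#' showing DNA condensation (mean DNA intensity above `cond_factor` times
#' the interphase median), reduced area (below `area_factor` times the
#' median) and near-circular shape, or a bright mitosis marker. Events
#' below `0.5 * P` (debris guard) or above the G2 window are unclassified.
#'
#' @param mode `"edu"` or `"dna"`.
#' @param dna_col,edu_col,marker_col,area_col,circ_col column names.
#' @param g_lo,g_hi G1 window in G1-peak multiples.
#' @param cond_factor,area_factor,circ_min mitosis morphology thresholds.
#' @param edu_threshold EdU positivity threshold (`NULL` = automatic Otsu
#'   split of `log10(EdU)`).
#' @param marker_threshold mitosis-marker threshold (`NULL` = automatic:
#'   median + 5 MAD; `NA` disables the marker criterion).
#' @param use_morphology use the condensation/area/circularity criterion.
#' @return configuration list.
#' @export
cell_cycle_config <- function(mode = c("edu", "dna"),
                              dna_col = "dna_integrated",
                              edu_col = "edu_mean",
                              marker_col = "marker_mean",
                              area_col = "area_um2",
                              circ_col = "circularity",
                              g_lo = 0.8, g_hi = 1.25,
                              cond_factor = 1.5, area_factor = 0.8,
                              circ_min = 0.9,
                              edu_threshold = NULL, marker_threshold = NULL,
                              use_morphology = TRUE) {
  list(mode = match.arg(mode), dna_col = dna_col, edu_col = edu_col,
       marker_col = marker_col, area_col = area_col, circ_col = circ_col,
       g_lo = g_lo, g_hi = g_hi, cond_factor = cond_factor,
       area_factor = area_factor, circ_min = circ_min,
       edu_threshold = edu_threshold, marker_threshold = marker_threshold,
       use_morphology = use_morphology)
}

# Otsu threshold on a numeric vector (between-class variance maximisation)
.otsu_vector <- function(v, levels = 256) {
  h <- make_histogram(data.frame(v = v), "v", bins = levels)
  w <- h$counts / sum(h$counts)
  mu <- cumsum(w * h$mids); om <- cumsum(w)
  mt <- mu[levels]
  bc <- (mt * om - mu)^2 / (om * (1 - om))
  bc[!is.finite(bc)] <- -Inf
  h$mids[which.max(bc)]
}

# G1 peak: lowest local maximum of the smoothed DNA-content density whose
# height reaches 25% of the global mode (guards against G2-dominant samples)
.g1_peak <- function(dna) {
  dna <- dna[is.finite(dna) & dna > 0]
  if (length(dna) < 10)
    .stop2("classification_error", "too few events for a DNA-content peak")
  d <- stats::density(dna, bw = "nrd0")
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  locmax <- locmax[y[locmax] >= 0.25 * max(y)]
  if (!length(locmax))
    .stop2("classification_error", "no detectable G1 peak in the DNA histogram")
  d$x[min(locmax)]
}

#' Classify cells into cell-cycle phases
#'
#' See [cell_cycle_config()] for the decision rules. Classification is
#' invariant to uniform rescaling of the DNA intensity because all windows
#' are relative to the detected G1 peak.
#'
#' @param table cell table with the configured columns.
#' @param config a [cell_cycle_config()].
#' @return data.frame with `cell_id` and `phase` in
#'   `{G1, S, G2, M, unclassified}`, plus attribute `g1_peak`.
#' @export
classify_cell_cycle <- function(table, config = cell_cycle_config()) {
  dna <- table[[config$dna_col]]
  if (is.null(dna)) .stop2("parameter_error", "no column '%s'", config$dna_col)
  P <- .g1_peak(dna)
  phase <- rep("unclassified", nrow(table))
  in_g1 <- dna >= config$g_lo * P & dna <= config$g_hi * P
  in_g2 <- dna >= 2 * config$g_lo * P & dna <= 2 * config$g_hi * P
  between <- dna > config$g_hi * P & dna < 2 * config$g_lo * P
  subg1 <- dna < 0.5 * P

  if (config$mode == "edu") {
    edu <- table[[config$edu_col]]
    if (is.null(edu)) .stop2("parameter_error", "no column '%s'", config$edu_col)
    thr <- config$edu_threshold %||%
      10^.otsu_vector(log10(pmax(edu, 1e-6)))
    s <- edu > thr
    phase[s & !subg1] <- "S"
    phase[!s & in_g1] <- "G1"
    phase[!s & in_g2] <- "G2"
  } else {
    phase[in_g1] <- "G1"
    phase[in_g2] <- "G2"
    phase[between] <- "S"
  }

  # mitosis overlay among G2-window cells
  g2w <- phase == "G2"
  if (any(g2w)) {
    interphase <- phase %in% c("G1", "S", "G2")
    mit <- rep(FALSE, nrow(table))
    dna_mean_col <- sub("_integrated$", "_mean", config$dna_col)
    if (config$use_morphology && all(c(dna_mean_col, config$area_col,
                                       config$circ_col) %in% names(table))) {
      dm <- table[[dna_mean_col]]
      med_dm <- stats::median(dm[interphase])
      med_area <- stats::median(table[[config$area_col]][interphase])
      mit <- dm > config$cond_factor * med_dm &
        table[[config$area_col]] < config$area_factor * med_area &
        table[[config$circ_col]] > config$circ_min
    }
    marker_off <- length(config$marker_threshold) == 1 &&
      is.na(config$marker_threshold)
    mk <- table[[config$marker_col]]
    if (!marker_off && !is.null(mk)) {
      mthr <- config$marker_threshold %||%
        (stats::median(mk) + 5 * stats::mad(mk))
      mit <- mit | mk > mthr
    }
    phase[g2w & mit] <- "M"
  }
  out <- data.frame(cell_id = table$cell_id %||% seq_len(nrow(table)),
                    phase = phase, stringsAsFactors = FALSE)
  attr(out, "g1_peak") <- P
  out
}

#' Select event ids by gate membership or phase label
#'
#' @param table cell table (needs `cell_id`; `source_file` used for
#'   ordering when present).
#' @param membership logical vector over rows (e.g. one column of
#'   [apply_gates()] membership), or `NULL` when selecting by phase.
#' @param labels phase-label data.frame from [classify_cell_cycle()].
#' @param phase phase to select when `labels` is given.
#' @return integer/character vector of `cell_id`s, ordered by source file
#'   then id (deterministic).
#' @export
select_events <- function(table, membership = NULL, labels = NULL,
                          phase = NULL) {
  if (!is.null(labels)) {
    if (is.null(phase)) .stop2("parameter_error", "phase required with labels")
    ids <- labels$cell_id[labels$phase == phase]
    sel <- table$cell_id %in% ids
  } else if (!is.null(membership)) {
    sel <- as.logical(membership)
  } else .stop2("parameter_error", "give membership or labels+phase")
  sub <- table[sel, , drop = FALSE]
  key <- if ("source_file" %in% names(sub))
    order(as.character(sub$source_file), sub$cell_id) else order(sub$cell_id)
  sub$cell_id[key]
}
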