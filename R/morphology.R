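#' Construct a morphology from a section table
#'
#' A morphology is a rooted tree of cylindrical sections, each discretized
#' into `nseg` nodes of equal length (node centers at `(i - 0.5)/nseg`).
#' The first section is the root (usually the soma); every other section
#' names its parent and the normalized position `attach` (0-1) on the parent
#' where it connects.
#'
#' @param sections data.frame with columns `name`, `length` (um), `diam`
#'   (um), `nseg`, `parent` (name or `NA` for the root), `attach` (0-1),
#'   and optionally `role` ("soma"/"dend") and `cm` (uF/cm2).
#' @param ra axial resistivity, Ohm cm.
#' @return An object of class `morphology`.
#' @export
morphology <- function(sections, ra = .const$ra) {
  stopifnot(is.data.frame(sections))
  need <- c("name", "length", "diam", "nseg", "parent", "attach")
  miss <- setdiff(need, names(sections))
  if (length(miss) > 0) stop("sections is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(sections$role)) sections$role <- "dend"
  if (is.null(sections$cm)) sections$cm <- .const$cm
  if (any(duplicated(sections$name))) stop("duplicate section names")
  if (any(!is.finite(sections$length)) || any(sections$length <= 0))
    stop("all section lengths must be positive")
  if (any(!is.finite(sections$diam)) || any(sections$diam <= 0))
    stop("all section diameters must be positive")
  if (any(sections$nseg < 1)) stop("nseg must be >= 1 for every section")
  if (!is.na(sections$parent[1])) stop("first section must be the root (parent NA)")
  if (nrow(sections) > 1) {
    for (i in 2:nrow(sections)) {
      p <- sections$parent[i]
      if (is.na(p)) stop("only the first section may be the root")
      j <- match(p, sections$name)
      if (is.na(j)) stop("unknown parent section: ", p)
      if (j >= i) stop("parent sections must precede children (no cycles): ", p)
    }
  }
  if (any(sections$attach < 0 | sections$attach > 1))
    stop("attach positions must lie in [0, 1]")
  if (!is.finite(ra) || ra <= 0) stop("ra must be positive")
  structure(list(sections = sections, ra = ra), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  s <- x$sections
  cat(sprintf("<morphology> %d section(s), %d node(s), Ra = %g Ohm cm\n",
              nrow(s), sum(s$nseg), x$ra))
  cat(sprintf("  total length %.1f um, membrane area %.1f um2\n",
              sum(s$length), sum(pi * s$diam * s$length)))
  invisible(x)
}

#' Ball-and-stick morphology
#'
#' An isopotential soma (cylinder with length equal to its diameter, so the
#' lateral area equals the area pi*d^2 of a sphere of the same diameter) with
#' a single uniform dendrite attached at the soma.
#'
#' @param soma_diameter um (default 20).
#' @param dendrite_length um (default 200; 1000 for the long variant).
#' @param dendrite_diameter um (default 1).
#' @param n_dendrite_nodes number of dendritic nodes (default 103).
#' @return A `morphology`.
#' @export
#' @examples
#' m <- build_ball_and_stick()
#' m
build_ball_and_stick <- function(soma_diameter = 20, dendrite_length = 200,
                                 dendrite_diameter = 1, n_dendrite_nodes = 103) {
  if (any(c(soma_diameter, dendrite_length, dendrite_diameter) <= 0))
    stop("all dimensions must be positive")
  if (n_dendrite_nodes < 1) stop("n_dendrite_nodes must be >= 1")
  morphology(data.frame(
    name   = c("soma", "dend"),
    length = c(soma_diameter, dendrite_length),
    diam   = c(soma_diameter, dendrite_diameter),
    nseg   = c(1L, as.integer(n_dendrite_nodes)),
    parent = c(NA, "soma"),
    attach = c(0, 1),
    role   = c("soma", "dend"),
    stringsAsFactors = FALSE
  ))
}

#' Synthetic CA3-like surrogate morphology
#'
#' A stellate surrogate for an immature CA3 pyramidal cell: soma, a short
#' dendritic trunk, and `n_dendrites` identical thin dendrites attached at
#' the trunk tip. Dendrite length is a free parameter (see
#' [calibrate_dendrite_length()]); the default of 150 um is a realistic
#' immature-CA3 dendrite length.
#'
#' @param n_dendrites number of terminal dendrites (default 56).
#' @param trunk_length,trunk_diameter um (defaults 32 and 2).
#' @param dendrite_diameter um (default 0.36).
#' @param dendrite_length um (default 150).
#' @param segments_per_section nodes per trunk/dendrite section (default 9).
#' @param soma_diameter um (default 15).
#' @return A `morphology` with `1 + 1 + n_dendrites` sections.
#' @export
build_ca3_like <- function(n_dendrites = 56, trunk_length = 32, trunk_diameter = 2,
                           dendrite_diameter = 0.36, dendrite_length = 150,
                           segments_per_section = 9, soma_diameter = 15) {
  if (n_dendrites < 1) stop("n_dendrites must be >= 1")
  if (any(c(trunk_length, trunk_diameter, dendrite_diameter,
            dendrite_length, soma_diameter) <= 0))
    stop("all dimensions must be positive")
  if (segments_per_section < 1) stop("segments_per_section must be >= 1")
  dn <- sprintf("dend%d", seq_len(n_dendrites))
  morphology(data.frame(
    name   = c("soma", "trunk", dn),
    length = c(soma_diameter, trunk_length, rep(dendrite_length, n_dendrites)),
    diam   = c(soma_diameter, trunk_diameter, rep(dendrite_diameter, n_dendrites)),
    nseg   = c(1L, rep(as.integer(segments_per_section), 1 + n_dendrites)),
    parent = c(NA, "soma", rep("trunk", n_dendrites)),
    attach = c(0, 1, rep(1, n_dendrites)),
    role   = c("soma", "dend", rep("dend", n_dendrites)),
    stringsAsFactors = FALSE
  ))
}

# Per-node discretization table: geometry, membrane area, axial coupling.
# Columns: section, x (normalized center), dx (um), diam (um), area_cm2,
# cm_nF, parent (node index or NA), gax_uS (axial conductance to parent),
# ddx_um (center-to-center path distance to parent), path_um (distance from
# the root node center), role.
morph_nodes <- function(morph) {
  s <- morph$sections
  ra <- morph$ra
  out <- vector("list", nrow(s))
  first <- integer(nrow(s))  # index of first node of each section
  n_before <- 0L
  for (i in seq_len(nrow(s))) {
    n <- s$nseg[i]
    dx <- s$length[i] / n
    first[i] <- n_before + 1L
    # half-segment axial resistance in MOhm-compatible units:
    # r_half [Ohm] = Ra * (dx/2 cm) / (pi (d/2 cm)^2); conduct in uS = 1e6/r
    out[[i]] <- data.frame(
      section = s$name[i], x = (seq_len(n) - 0.5) / n, dx = dx,
      diam = s$diam[i], area_cm2 = pi * s$diam[i] * dx * 1e-8,
      cm_nF = s$cm[i] * pi * s$diam[i] * dx * 1e-8 * 1e3,
      parent = NA_integer_, gax_uS = NA_real_, ddx_um = NA_real_,
      path_um = NA_real_, role = s$role[i], stringsAsFactors = FALSE
    )
    n_before <- n_before + n
  }
  nodes <- do.call(rbind, out)
  r_half <- function(k) {  # Ohm, half-segment of node k
    ra * (nodes$dx[k] / 2 * 1e-4) / (pi * (nodes$diam[k] / 2 * 1e-4)^2)
  }
  row0 <- 0L
  for (i in seq_len(nrow(s))) {
    n <- s$nseg[i]
    idx <- row0 + seq_len(n)
    if (i > 1) {
      pj <- match(s$parent[i], s$name)
      pn <- s$nseg[pj]
      pk <- first[pj] + pmin(pn - 1L, floor(s$attach[i] * pn))  # node containing attach pos
      k <- idx[1]
      nodes$parent[k] <- pk
      nodes$gax_uS[k] <- 1e6 / (r_half(k) + r_half(pk))
      nodes$ddx_um[k] <- nodes$dx[k] / 2 + nodes$dx[pk] / 2
    }
    if (n > 1) {
      for (k in idx[-1]) {
        nodes$parent[k] <- k - 1L
        nodes$gax_uS[k] <- 1e6 / (r_half(k) + r_half(k - 1L))
        nodes$ddx_um[k] <- nodes$dx[k]
      }
    }
    row0 <- row0 + n
  }
  nodes$path_um[1] <- 0
  for (k in seq_len(nrow(nodes))[-1])
    nodes$path_um[k] <- nodes$path_um[nodes$parent[k]] + nodes$ddx_um[k]
  nodes
}

# nearest node center to position x on a named section
probe_node <- function(nodes, section, x) {
  idx <- which(nodes$section == section)
  if (length(idx) == 0) stop("no such section: ", section)
  idx[which.min(abs(nodes$x[idx] - x))]
}

#' Steady-state somatic input resistance
#'
#' Solves the discretized steady cable equation with a uniform passive
#' conductance and returns the voltage deflection per unit current injected
#' at the root (somatic) node.
#'
#' @param morph a [morphology()].
#' @param passive_conductance S/cm2 (default 1 mS/cm2).
#' @param at node index at which to inject/measure (default 1, the root).
#' @return Input resistance in MOhm.
#' @export
#' @examples
#' input_resistance(build_ball_and_stick())
input_resistance <- function(morph, passive_conductance = .const$g_pas, at = 1L) {
  if (!is.finite(passive_conductance) || passive_conductance <= 0)
    stop("passive_conductance must be positive (zero gives unbounded resistance)")
  nodes <- morph_nodes(morph)
  n <- nrow(nodes)
  G <- matrix(0, n, n)
  diag(G) <- passive_conductance * nodes$area_cm2 * 1e6  # uS
  for (k in seq_len(n)[-1]) {
    p <- nodes$parent[k]
    g <- nodes$gax_uS[k]
    G[k, k] <- G[k, k] + g
    G[p, p] <- G[p, p] + g
    G[k, p] <- G[k, p] - g
    G[p, k] <- G[p, k] - g
  }
  I <- numeric(n)
  I[at] <- 1  # nA
  v <- solve(G, I)  # mV; mV/nA = MOhm
  unname(v[at])
}

#' Calibrate the surrogate dendrite length against an input-resistance target
#'
#' Bisects the terminal-dendrite length of the CA3-like surrogate so that
#' the somatic input resistance matches a target. Input resistance decreases
#' monotonically with dendrite length; if the target lies outside the range
#' achievable within `bounds`, the closest bracket end is returned with a
#' warning. (With the default passive parameters the isopotential soma alone
#' caps the whole-cell input resistance near 134 MOhm, so targets above that
#' are unreachable for any length.)
#'
#' @param target_rin MOhm.
#' @param passive_conductance S/cm2.
#' @param bounds length bracket in um.
#' @param tol convergence tolerance on R_in, MOhm.
#' @param ... passed to [build_ca3_like()].
#' @return Calibrated dendrite length, um.
#' @export
calibrate_dendrite_length <- function(target_rin = 188.2,
                                      passive_conductance = .const$g_pas,
                                      bounds = c(5, 2000), tol = 0.01, ...) {
  rin <- function(L) input_resistance(build_ca3_like(dendrite_length = L, ...),
                                      passive_conductance)
  lo <- bounds[1]; hi <- bounds[2]
  r_lo <- rin(lo); r_hi <- rin(hi)  # r_lo > r_hi
  if (target_rin >= r_lo) {
    warning(sprintf(paste0("target %.1f MOhm is above the achievable range ",
                           "[%.1f, %.1f] MOhm; returning the shortest length"),
                    target_rin, r_hi, r_lo))
    return(lo)
  }
  if (target_rin <= r_hi) {
    warning(sprintf(paste0("target %.1f MOhm is below the achievable range ",
                           "[%.1f, %.1f] MOhm; returning the longest length"),
                    target_rin, r_hi, r_lo))
    return(hi)
  }
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    r <- rin(mid)
    if (abs(r - target_rin) < tol) return(mid)
    if (r > target_rin) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read an SWC morphology
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent). Chains of points between branch points become sections whose
#' length is the summed 3D point-to-point distance and whose diameter is the
#' length-weighted mean of the point diameters; soma points (type 1) are
#' collapsed into a single isopotential root section.
#'
#' @param source path to an SWC file, or a character vector of SWC lines.
#' @param spacing target node spacing in um used to pick `nseg` per section
#'   (default 10).
#' @return A `morphology`.
#' @export
read_swc <- function(source, spacing = 10) {
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source) else source
  pts <- list(); ids <- integer(0)
  for (ln in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(txt))) next
    f <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(f) != 7 || anyNA(f))
      stop(sprintf("malformed SWC line %d: %s", ln, trimws(lines[ln])))
    id <- as.integer(f[1]); parent <- as.integer(f[7])
    if (id %in% ids) stop(sprintf("SWC line %d: duplicate id %d", ln, id))
    if (parent != -1 && !(parent %in% ids))
      stop(sprintf("SWC line %d: parent id %d not defined yet", ln, parent))
    if (f[6] <= 0) stop(sprintf("SWC line %d: non-positive radius", ln))
    ids <- c(ids, id)
    pts[[as.character(id)]] <- list(id = id, type = f[2], xyz = f[3:5],
                                    r = f[6], parent = parent)
  }
  if (length(pts) == 0) stop("empty SWC input")
  if (sum(vapply(pts, function(p) p$parent == -1, logical(1))) != 1)
    stop("SWC input must have exactly one root point")
  kids <- lapply(pts, function(p) integer(0))
  for (p in pts) if (p$parent != -1)
    kids[[as.character(p$parent)]] <- c(kids[[as.character(p$parent)]], p$id)
  soma_ids <- ids[vapply(pts, function(p) p$type == 1, logical(1))]
  sec_of <- character(0)
  secs <- NULL
  if (length(soma_ids) > 0) {
    soma_d <- 2 * mean(vapply(pts[as.character(soma_ids)], `[[`, numeric(1), "r"))
    secs <- data.frame(name = "soma", length = soma_d, diam = soma_d, nseg = 1L,
                       parent = NA_character_, attach = 0, role = "soma",
                       stringsAsFactors = FALSE)
    sec_of <- setNames(rep("soma", length(soma_ids)), as.character(soma_ids))
  }
  # section starts: the (non-soma) root, children of soma points, children of
  # branch points
  is_start <- function(p) {
    if (p$type == 1) return(FALSE)
    if (p$parent == -1) return(TRUE)
    pp <- pts[[as.character(p$parent)]]
    pp$type == 1 || length(kids[[as.character(pp$id)]]) > 1
  }
  starts <- ids[vapply(pts, is_start, logical(1))]
  ctr <- 0L
  for (st in starts) {
    ctr <- ctr + 1L
    name <- sprintf("neurite%d", ctr)
    len <- 0; dsum <- 0
    cur <- pts[[as.character(st)]]
    repeat {
      if (cur$parent != -1) {
        prev <- pts[[as.character(cur$parent)]]
        seg <- sqrt(sum((cur$xyz - prev$xyz)^2))
        dedge <- if (prev$type == 1) 2 * cur$r else cur$r + prev$r
        len <- len + seg
        dsum <- dsum + seg * dedge
      }
      sec_of[as.character(cur$id)] <- name
      ch <- kids[[as.character(cur$id)]]
      if (length(ch) != 1) break
      nxt <- pts[[as.character(ch)]]
      if (nxt$type == 1 || is_start(nxt)) break
      cur <- nxt
    }
    if (len <= 0) stop("SWC section of zero length starting at point ", st)
    proot <- pts[[as.character(st)]]$parent
    pname <- if (proot == -1) NA_character_ else unname(sec_of[as.character(proot)])
    secs <- rbind(secs, data.frame(
      name = name, length = len, diam = dsum / len,
      nseg = max(1L, as.integer(ceiling(len / spacing))),
      parent = pname, attach = 1, role = "dend", stringsAsFactors = FALSE))
  }
  morphology(secs)
}
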