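# Pure-R reference integrator mirroring the compiled engine step for step:
# event delivery -> conductance evaluation (analytic mid-step value,
# reversals frozen at step start) -> dense Crank-Nicolson cable solve ->
# anion flux at the mid-step voltage -> implicit radial and longitudinal
# diffusion -> exact-exponential relaxation. Dense linear algebra
# throughout; usable only for small node counts. Serves as the
# independent oracle for the compiled tree solver.

reference_integrate <- function(morph, mechanisms, schedule, ions, config) {
  nodes <- ions$nodes
  n <- nrow(nodes)
  pas <- mechanisms$passive
  dt <- config$dt
  theta <- config$theta
  n_steps <- as.integer(ceiling(config$duration / dt))
  rtf <- chloridyn_constants()$gas *
    (config$temperature + 273.15) / chloridyn_constants()$faraday * 1e3

  leak_on <- if (is.null(pas$sections)) rep(TRUE, n) else
    nodes$section %in% pas$sections
  gl <- pas$g_pas * nodes$area_cm2 * 1e6 * leak_on
  cmn <- nodes$cm_nF

  tgcl <- tghc <- numeric(n)
  if (!is.null(mechanisms$tonic)) {
    tn <- mechanisms$tonic
    on <- if (is.null(tn$sections)) rep(TRUE, n) else
      nodes$section %in% tn$sections
    gtn <- tn$density * nodes$area_cm2 * 1e6 * on
    tgcl <- gtn / (1 + tn$p)
    tghc <- gtn * tn$p / (1 + tn$p)
  }

  syns <- mechanisms$synapses
  ids <- names(syns)
  sn <- vapply(syns, function(s)
    chloridyn:::probe_node(nodes, s$section, s$x), 1L)
  samp <- vapply(syns, function(s)
    s$g_max * chloridyn:::exp2_norm(s$tau1, s$tau2), 1)
  dec1 <- vapply(syns, function(s) exp(-dt / s$tau1), 1)
  dec2 <- vapply(syns, function(s) exp(-dt / s$tau2), 1)
  hdec1 <- vapply(syns, function(s) exp(-0.5 * dt / s$tau1), 1)
  hdec2 <- vapply(syns, function(s) exp(-0.5 * dt / s$tau2), 1)
  A <- B <- numeric(length(syns))
  ev <- schedule[order(schedule$time), , drop = FALSE]
  ev_idx <- match(ev$synapse, ids)
  ev_ptr <- 1L

  state <- ions
  tr <- state$transport
  v <- rep(pas$e_pas, n)

  # axial conductance matrix (uS)
  L <- matrix(0, n, n)
  for (k in seq_len(n)[-1]) {
    p <- nodes$parent[k]
    g <- nodes$gax_uS[k]
    L[k, k] <- L[k, k] + g; L[p, p] <- L[p, p] + g
    L[k, p] <- L[k, p] - g; L[p, k] <- L[p, k] - g
  }

  probes <- vapply(seq_len(nrow(config$probes)), function(i)
    chloridyn:::probe_node(nodes, config$probes$section[i], config$probes$x[i]), 1L)
  stride <- max(1L, as.integer(round(config$record_every / dt)))
  if (n_steps %% stride != 0L) n_steps <- n_steps + (stride - n_steps %% stride)
  n_rec <- n_steps / stride + 1
  rec_t <- numeric(n_rec)
  rec_v <- matrix(NA_real_, n_rec, length(probes))
  rec_cl <- matrix(NA_real_, n_rec, length(probes))
  rec <- 1L
  rec_t[1] <- 0; rec_v[1, ] <- v[probes]; rec_cl[1, ] <- state$cl[probes, 5]

  for (step in seq_len(n_steps)) {
    t <- (step - 1) * dt
    while (ev_ptr <= nrow(ev) && ev$time[ev_ptr] <= t + 1e-9) {
      s <- ev_idx[ev_ptr]
      A[s] <- A[s] + samp[s]; B[s] <- B[s] + samp[s]
      ev_ptr <- ev_ptr + 1L
    }
    gtot <- gl
    ge <- gl * pas$e_pas
    ecl_n <- rtf * log(state$cl[, 5] / state$cl_out)
    ehc_n <- rtf * log(state$hco3[, 5] / state$hco3_out)
    ton <- tgcl > 0 | tghc > 0
    gtot[ton] <- gtot[ton] + tgcl[ton] + tghc[ton]
    ge[ton] <- ge[ton] + tgcl[ton] * ecl_n[ton] + tghc[ton] * ehc_n[ton]
    sgcl <- sghc <- secl <- sehc <- numeric(length(syns))
    for (s in seq_along(syns)) {
      g <- (B[s] * hdec2[s] - A[s] * hdec1[s]) * 1e-3
      if (g <= 0) next
      i <- sn[s]
      if (syns[[s]]$kind == "gaba") {
        ecl <- rtf * log(state$cl[i, 5] / state$cl_out)
        ehc <- rtf * log(state$hco3[i, 5] / state$hco3_out)
        p <- syns[[s]]$p
        sgcl[s] <- g / (1 + p); sghc[s] <- g * p / (1 + p)
        secl[s] <- ecl; sehc[s] <- ehc
        gtot[i] <- gtot[i] + g
        ge[i] <- ge[i] + sgcl[s] * ecl + sghc[s] * ehc
      } else if (syns[[s]]$kind == "ampa") {
        gtot[i] <- gtot[i] + g
        ge[i] <- ge[i] + g * syns[[s]]$e_rev
      } else {
        blk <- nmda_block(v[i], syns[[s]]$mg, syns[[s]]$mg_slope,
                          syns[[s]]$mg_scale)
        gtot[i] <- gtot[i] + g * blk
        ge[i] <- ge[i] + g * blk * syns[[s]]$e_rev
      }
    }
    M <- diag(cmn / dt + theta * gtot, n) + theta * L
    b <- cmn / dt * v - (1 - theta) * (gtot * v) + ge -
      (1 - theta) * as.vector(L %*% v)
    v_new <- solve(M, b)
    for (s in seq_along(syns)) {
      if (sgcl[s] <= 0 && sghc[s] <= 0) next
      i <- sn[s]
      vm <- 0.5 * (v[i] + v_new[i])
      icl <- sgcl[s] * (vm - secl[s])
      ihc <- sghc[s] * (vm - sehc[s])
      state$cl[i, 5] <- state$cl[i, 5] +
        apply_flux(icl, state$geom$vol[i, 5], dt)
      state$hco3[i, 5] <- state$hco3[i, 5] +
        apply_flux(ihc, state$geom$vol[i, 5], dt)
    }
    for (i in which(ton)) {
      vm <- 0.5 * (v[i] + v_new[i])
      state$cl[i, 5] <- state$cl[i, 5] +
        apply_flux(tgcl[i] * (vm - ecl_n[i]), state$geom$vol[i, 5], dt)
      state$hco3[i, 5] <- state$hco3[i, 5] +
        apply_flux(tghc[i] * (vm - ehc_n[i]), state$geom$vol[i, 5], dt)
    }
    if (isTRUE(config$diffusion)) {
      state <- radial_step(state, dt)
      state <- longitudinal_step(state, dt)
    }
    if (isTRUE(config$transport)) state <- relaxation_step(state, dt)
    A <- A * dec1; B <- B * dec2
    v <- v_new
    if (step %% stride == 0) {
      rec <- rec + 1L
      rec_t[rec] <- step * dt
      rec_v[rec, ] <- v[probes]
      rec_cl[rec, ] <- state$cl[probes, 5]
    }
  }
  list(time = rec_t, v = rec_v, cl = rec_cl, state = state, v_final = v)
}

# dense steady-state passive solve: voltage profile for current injection
steady_voltage <- function(morph, g_pas, inj_node, inj_nA) {
  nodes <- chloridyn:::morph_nodes(morph)
  n <- nrow(nodes)
  G <- diag(g_pas * nodes$area_cm2 * 1e6, n)
  for (k in seq_len(n)[-1]) {
    p <- nodes$parent[k]
    g <- nodes$gax_uS[k]
    G[k, k] <- G[k, k] + g; G[p, p] <- G[p, p] + g
    G[k, p] <- G[k, p] - g; G[p, k] <- G[p, k] - g
  }
  I <- numeric(n); I[inj_node] <- inj_nA
  list(nodes = nodes, v = solve(G, I))
}
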