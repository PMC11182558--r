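# Model core: opinion allocation, instantaneous flows, one Euler step.
#
# Internally the engine works on a plain numeric state vector (fixed
# layout below) for speed; the exported functions wrap/unwrap tidy
# structures around the same internal math so the fast path and the
# documented path cannot diverge.

# state vector layout (persons unless noted)
.S <- c(
  t = 1L, undecided = 2L, P = 3L, PI = 4L, PIP = 5L, N = 6L, NI = 7L,
  NE = 8L, NIN = 9L, exited_cum = 10L, entered_cum = 11L, pending = 12L,
  heat_active = 13L # 0/1 latch: has NE ever exceeded heat_threshold
)

# flow vector layout (persons/day)
.F <- c(
  entry_neg = 1L, entry_pos = 2L,
  v1 = 3L, v2 = 4L, v3 = 5L, v4 = 6L, v5 = 7L, v6 = 8L, v7 = 9L,
  v8 = 10L, v9 = 11L, v10 = 12L, v11 = 13L,
  exit_P = 14L, exit_PI_to_PIP = 15L, exit_N = 16L, exit_NI = 17L,
  exit_NIN = 18L, exit_NE = 19L
)

#' A model state at one time point
#'
#' Builds the full bookkeeping state of the opinion field at one time:
#' the undecided pool, the seven opinion stocks, cumulative entries and
#' exits, the not-yet-entered pending pool and the heat-reduction latch.
#'
#' @param t Model time (days, `>= 0`).
#' @param undecided,P,PI,PIP,N,NI,NE,NIN Stock occupancies (persons,
#'   non-negative reals).
#' @param exited_cum Cumulative persons that left the opinion field.
#' @param entered_cum Cumulative persons that ever entered. Defaults to
#'   the sum of all stocks plus `exited_cum` so a hand-built state is
#'   conservative by construction.
#' @param pending Persons scheduled to enter later (delayed entry).
#' @param heat_active Has `NE` ever exceeded the heat threshold?
#'
#' @return A `gp_state` object (named list).
#' @examples
#' gp_state(NI = 10)
#' @export
gp_state <- function(t = 0, undecided = 0, P = 0, PI = 0, PIP = 0,
                     N = 0, NI = 0, NE = 0, NIN = 0, exited_cum = 0,
                     entered_cum = NULL, pending = 0,
                     heat_active = FALSE) {
  stocks <- c(undecided, P, PI, PIP, N, NI, NE, NIN)
  if (any(!is.finite(stocks)) || any(stocks < 0)) {
    abort("all stocks must be finite and >= 0 (persons)")
  }
  if (!is.finite(t) || t < 0) abort("`t` must be >= 0 (days)")
  entered_cum <- entered_cum %||% (sum(stocks) + exited_cum)
  structure(list(
    t = t, undecided = undecided, P = P, PI = PI, PIP = PIP, N = N,
    NI = NI, NE = NE, NIN = NIN, exited_cum = exited_cum,
    entered_cum = entered_cum, pending = pending,
    heat_active = isTRUE(heat_active) || isTRUE(heat_active == 1)
  ), class = "gp_state")
}

state_to_vec <- function(state) {
  v <- c(state$t, state$undecided, state$P, state$PI, state$PIP,
         state$N, state$NI, state$NE, state$NIN, state$exited_cum,
         state$entered_cum, state$pending,
         as.numeric(isTRUE(state$heat_active)))
  v
}

vec_to_state <- function(v) {
  gp_state(
    t = v[1L], undecided = v[2L], P = v[3L], PI = v[4L], PIP = v[5L],
    N = v[6L], NI = v[7L], NE = v[8L], NIN = v[9L], exited_cum = v[10L],
    entered_cum = v[11L], pending = v[12L], heat_active = v[13L] > 0
  )
}

#' Allocate undecided users to positive or negative opinions
#'
#' Social-comparison entry rule: an undecided user forms a negative
#' opinion with probability `lambda5 * p_neg` and a positive one with
#' probability `(1 - lambda5) * p_pos`, where `p_neg = N/(P+N)` and
#' `p_pos = P/(P+N)` once both camps hold at least one whole person.
#' While the smaller camp holds fewer than one person the shares ramp
#' linearly back towards the `0.5` coin flip (a sub-person camp is not
#' observable to an entrant, and the bare ratio is singular at the
#' empty origin). The remainder stays undecided until a later step;
#' `Sn + Sp <= undecided` always.
#'
#' @param undecided Persons with no formed opinion (`>= 0`).
#' @param params A [gp_params()] object (only `lambda5` is used).
#' @param P,N Current positive / negative opinion stocks (persons).
#' @param mode `"meanfield"` for the expected allocation,
#'   `"stochastic"` for a multinomial draw over `floor(undecided)`
#'   users (uses the current RNG stream).
#' @param strict_integer Floor the mean-field allocations to whole
#'   persons.
#'
#' @return A list with components `Sn` (to negative) and `Sp` (to
#'   positive), in persons.
#' @examples
#' allocate_opinions(100, gp_params(lambda5 = 0.2))
#' @export
allocate_opinions <- function(undecided, params, P = 0, N = 0,
                              mode = c("meanfield", "stochastic"),
                              strict_integer = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(undecided) || undecided < 0 || !is.finite(P) || P < 0 ||
      !is.finite(N) || N < 0) {
    abort("`undecided`, `P` and `N` must be finite and >= 0")
  }
  l5 <- params$lambda5
  # the camp-size ratio is only observable once both camps hold at
  # least one whole person; below that entrants fall back towards the
  # coin flip. The linear ramp keeps the rule continuous in the state
  # (the bare ratio is singular at the empty-field origin).
  w <- max(0, min(1, P, N))
  if (P + N > 0) {
    p_neg <- w * N / (P + N) + (1 - w) * 0.5
    p_pos <- w * P / (P + N) + (1 - w) * 0.5
  } else {
    p_neg <- p_pos <- 0.5
  }
  if (mode == "stochastic") {
    size <- floor(undecided)
    if (size < 1) return(list(Sn = 0, Sp = 0))
    draw <- rmultinom(1L, size = size,
                      prob = c(l5 * p_neg, (1 - l5) * p_pos,
                               1 - l5 * p_neg - (1 - l5) * p_pos))
    return(list(Sn = draw[1L, 1L], Sp = draw[2L, 1L]))
  }
  Sn <- undecided * l5 * p_neg
  Sp <- undecided * (1 - l5) * p_pos
  if (isTRUE(strict_integer)) {
    Sn <- floor(Sn)
    Sp <- floor(Sp)
  }
  list(Sn = Sn, Sp = Sp)
}

# Raw flow computation on the internal vector state. Returns the flow
# vector (persons/day, layout .F), already clamped so that no stock can
# be driven negative within one step of length cf$dt.
flows_raw <- function(s, pr, cf, stochastic = FALSE) {
  t <- s[1L]; U <- s[2L]; P <- s[3L]; PI <- s[4L]
  N <- s[6L]; NI <- s[7L]; NE <- s[8L]; NIN <- s[9L]
  dt <- cf$dt
  heat_on <- s[13L] > 0 || NE > cf$heat_threshold

  # the allocation of the undecided pool acts as a continuous flow:
  # Sn persons (re-)form a negative opinion per day
  alloc <- allocate_opinions(U, pr, P = P, N = N,
                             mode = if (stochastic) "stochastic" else "meanfield",
                             strict_integer = cf$strict_integer)
  entry_neg <- alloc$Sn
  entry_pos <- alloc$Sp

  h <- t / cf$exit_scale_days
  r <- NIN / max(NE, cf$epsilon)

  v1 <- P * pr$lambda6 / pr$T_pi
  v3 <- N * pr$lambda6 / pr$T_ni
  v4 <- NI / pr$T_e
  v5 <- NI * pr$lambda2 / pr$T_c
  v6 <- PI / pr$T_c
  if (stochastic) {
    gate <- runif(1L) < min(1, r)
    v7 <- if (gate) PI * pr$lambda4 / (pr$T_c * pr$T_e) else 0
  } else {
    v7 <- PI * pr$lambda4 * min(1, r) / (pr$T_c * pr$T_e)
  }
  v9 <- NI * pr$lambda2 / pr$T_ef
  v10 <- if (heat_on) NIN * pr$lambda4 / pr$T_e * min(r, cf$ratio_cap) else 0
  v11 <- if (heat_on) NE * pr$lambda3 / pr$T_ef else 0

  exit_P <- P * h
  exit_N <- N * h
  exit_NI <- NI * h
  exit_NIN <- NIN * h
  exit_PI <- PI * h # lifecycle exit of PI, realized as the PI -> PIP flow
  exit_NE <- NE * t / (pr$T_ef * cf$exit_scale_days)

  # proportional rescaling: total outflow of a stock over one dt may not
  # exceed the stock
  clamp <- function(stock, total) {
    if (total * dt > stock) stock / (total * dt) else 1
  }
  cU <- clamp(U, entry_neg + entry_pos)
  entry_neg <- entry_neg * cU; entry_pos <- entry_pos * cU
  cP <- clamp(P, v1 + exit_P)
  v1 <- v1 * cP; exit_P <- exit_P * cP
  cN <- clamp(N, v3 + exit_N)
  v3 <- v3 * cN; exit_N <- exit_N * cN
  cNI <- clamp(NI, v4 + v5 + v9 + exit_NI)
  v4 <- v4 * cNI; v5 <- v5 * cNI; v9 <- v9 * cNI; exit_NI <- exit_NI * cNI
  cPI <- clamp(PI, v6 + v7 + exit_PI)
  v6 <- v6 * cPI; v7 <- v7 * cPI; exit_PI <- exit_PI * cPI
  cNIN <- clamp(NIN, v10 + exit_NIN)
  v10 <- v10 * cNIN; exit_NIN <- exit_NIN * cNIN
  cNE <- clamp(NE, v11 + exit_NE)
  v11 <- v11 * cNE; exit_NE <- exit_NE * cNE

  c(entry_neg, entry_pos,
    v1, exit_PI, v3, v4, v5, v6, v7, 0, v9, v10, v11,
    exit_P, exit_PI, exit_N, exit_NI, exit_NIN, exit_NE)
}

#' Instantaneous flows out of a model state
#'
#' Evaluates every transfer rate (persons/day) defined by the model at
#' one state: the entry allocations, the eleven named transition flows
#' and the lifecycle exits. Rates are pre-clamped by proportional
#' rescaling so that no stock can be driven negative within one Euler
#' step of the configured `dt`.
#'
#' The named flows are: `v1` positive opinion holders start interacting
#' (`P * lambda6 / T_pi`); `v2` positive keepers retire to the terminal
#' `PIP` stock (lifecycle, `PI * h(t)`); `v3` negative holders start
#' interacting (`N * lambda6 / T_ni`); `v4` interaction radicalises
#' (`NI / T_e`); `v5` emotional guidance converts negative to positive
#' (`NI * lambda2 / T_c`; also covers the described
#' negative-to-positive post-discussion pathway, so `v8 = 0`); `v6`
#' positive interactors drift negative (`PI / T_c`); `v7`
#' event-coupling pushes positive interactors straight to extreme
#' (`PI * lambda4 * min(1, NIN/NE) / (T_c * T_e)`; Bernoulli-gated in
#' stochastic mode); `v9` guidance de-escalates to non-extreme
#' (`NI * lambda2 / T_ef`); `v10` event-coupling escalates non-extreme
#' to extreme (`NIN * lambda4 / T_e * min(NIN/NE, cap)`); `v11` heat
#' reduction de-escalates extremes (`NE * lambda3 / T_ef`). `v10` and
#' `v11` are latched off until `NE` first exceeds `heat_threshold`.
#' Lifecycle exits use the hazard `h(t) = t / exit_scale_days`; the
#' extreme stock exits at `NE * t / (T_ef * exit_scale_days)`.
#'
#' @param state A [gp_state()].
#' @param params A [gp_params()] object.
#' @param config A [gp_config()]; supplies `dt`, guards, gating mode.
#'
#' @return A one-row tibble of flows (persons/day).
#' @examples
#' compute_flows(gp_state(NI = 10), gp_params(), gp_config())
#' @export
compute_flows <- function(state, params, config) {
  f <- flows_raw(state_to_vec(state), params, config,
                 stochastic = config$mode == "stochastic")
  as_tibble(as.list(setNames(f, names(.F))))
}

# Raw Euler step on the internal vector state. `f` must come from
# flows_raw() evaluated at `s`.
step_raw <- function(s, f, pr, cf) {
  dt <- cf$dt
  t <- s[1L]
  entry <- s[12L] / cf$entry_time # delayed entrants, persons/day
  Sn <- f[1L] * dt; Sp <- f[2L] * dt
  v1 <- f[3L]; v3 <- f[5L]; v4 <- f[6L]; v5 <- f[7L]; v6 <- f[8L]
  v7 <- f[9L]; v9 <- f[11L]; v10 <- f[12L]; v11 <- f[13L]
  exit_P <- f[14L]; exit_PI <- f[15L]; exit_N <- f[16L]
  exit_NI <- f[17L]; exit_NIN <- f[18L]; exit_NE <- f[19L]

  out <- s
  out[1L] <- t + dt
  out[2L] <- s[2L] - Sn - Sp + dt * entry                        # undecided
  out[3L] <- s[3L] + Sp + dt * (-v1 - exit_P)                    # P
  out[4L] <- s[4L] + dt * (v1 + v5 - v6 - v7 - exit_PI)          # PI
  out[5L] <- s[5L] + dt * exit_PI                                # PIP
  out[6L] <- s[6L] + Sn + dt * (-v3 - exit_N)                    # N
  out[7L] <- s[7L] + dt * (v3 - v4 - v5 - v9 - exit_NI)          # NI
  out[8L] <- s[8L] + dt * (v4 + v7 + v10 - v11 - exit_NE)        # NE
  out[9L] <- s[9L] + dt * (v9 + v6 + v11 - v10 - exit_NIN)       # NIN
  out[10L] <- s[10L] + dt * (exit_P + exit_N + exit_NI + exit_NIN + exit_NE)
  out[11L] <- s[11L] + dt * entry                                # entered_cum
  out[12L] <- s[12L] - dt * entry                                # pending
  # snap floating-point dust from exact clamping
  idx <- c(2:9, 12L)
  small <- idx[out[idx] < 0 & out[idx] > -1e-12]
  out[small] <- 0
  if (out[8L] > cf$heat_threshold) out[13L] <- 1
  out
}

#' Advance a model state by one Euler step
#'
#' Applies `dt * (inflows - outflows)` to every stock, moves the
#' per-step entry allocations, advances the delayed-entry schedule and
#' the cumulative entry/exit ledgers, and updates the heat-reduction
#' latch. The conservation identity (stocks + cumulative exits equal
#' cumulative entries) is preserved exactly.
#'
#' @param state A [gp_state()] the flows were computed from.
#' @param params A [gp_params()] object.
#' @param config A [gp_config()] (its `dt` is the step taken).
#' @param flows Flows from [compute_flows()] evaluated at `state`.
#'
#' @return The [gp_state()] at `t + dt`.
#' @examples
#' st <- gp_state(NI = 10)
#' cfg <- gp_config()
#' gp_step(st, cfg$params, cfg, compute_flows(st, cfg$params, cfg))
#' @export
gp_step <- function(state, params, config, flows) {
  if (!is.finite(config$dt) || config$dt <= 0) abort("`dt` must be > 0")
  f <- as.numeric(flows[1, names(.F)])
  vec_to_state(step_raw(state_to_vec(state), f, params, config))
}
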