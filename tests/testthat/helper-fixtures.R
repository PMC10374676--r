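# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

pop_params <- function() fixture("pop_params", default_parameters)

# a noise-free FLOT patient generated at a known parameter vector
noisefree_patient <- function() {
  fixture("noisefree_patient", function() {
    truth <- c(b_S_act = 1.3, b_A_CM = 0.8, PD_oxali = 1.2, PD_5FU = 0.3,
               w_PLC = 2.4)
    p_i <- set_individual(pop_params(), truth)
    ev <- build_dosing_events("FLOT", 1.8, 4)
    sched <- study_schedule(4)
    grid <- sort(unique(c(0, sched, seq(0, 59, by = 1))))
    traj <- simulate_hematopoiesis(p_i, ev, grid)
    obs <- observe(traj, sched, noise_cv = 0)
    list(truth = truth, params = p_i, events = ev, trajectory = traj,
         observations = obs,
         patient = list(patient_id = "NF1", regimen = "FLOT", BSA = 1.8,
                        observations = obs))
  })
}

# construct an ad-hoc linear PK model without touching the packaged configs
make_pk <- function(n, V, k10, k12 = 0, k21 = 0, k13 = 0, k31 = 0,
                    drug = "oxaliplatin") {
  structure(list(drug_id = drug, n_compartments = n, central_volume = V,
                 k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31),
            class = "hematotox_pk")
}

# independent infusion-schedule oracle for linear PK: piecewise solution by
# augmented matrix exponential (state extended with a constant-rate slot)
pk_infusion_oracle <- function(pk, events, t_grid) {
  M <- hematotox:::pk_matrix(pk)
  n <- nrow(M)
  brk <- sort(unique(c(t_grid[1], max(t_grid), events$start,
                       events$start + events$duration)))
  brk <- brk[brk >= t_grid[1] & brk <= max(t_grid)]
  a_cur <- rep(0, n)
  out <- numeric(length(t_grid))
  out[t_grid == brk[1]] <- 0
  step <- function(a0, rate, dt) {
    A <- rbind(cbind(M, c(rate, rep(0, n - 1))), 0)
    res <- as.matrix(Matrix::expm(A * dt)) %*% c(a0, 1)
    res[seq_len(n)]
  }
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]; b <- brk[i + 1]
    mid <- (a + b) / 2
    rate <- sum(events$rate[events$start <= mid &
                              events$start + events$duration > mid])
    inside <- t_grid[t_grid > a & t_grid <= b]
    for (tt in inside) {
      out[t_grid == tt] <- step(a_cur, rate, tt - a)[1] / pk$central_volume
    }
    a_cur <- step(a_cur, rate, b - a)
  }
  out
}

# brute-force Spearman: explicit average ranks + explicit Pearson formula
spearman_bruteforce <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
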