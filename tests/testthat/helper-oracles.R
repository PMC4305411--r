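# Shared oracles and reference implementations, independent of the code
# paths they check.

# closed-form isolated-cell steady state: nu_p (expr - c)(100 - c) = nu_n c,
# solved for the complex level c (smaller root)
steady_state_EB <- function(nu_p = 0.02, nu_n = 0.6, expr = 100, beta = 100) {
  # nu_p c^2 - (nu_p (expr + beta) + nu_n) c + nu_p expr beta = 0
  a <- nu_p
  b <- -(nu_p * (expr + beta) + nu_n)
  cc <- nu_p * expr * beta
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# central finite difference
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# cell <-> world adapters for the reference engine
world_cell <- function(world, idx) {
  cells <- world$cells
  id <- cells$id[idx]
  con <- world$contacts
  mine <- con$cell_i == id | con$cell_j == id
  sites <- data.frame(
    partner = ifelse(con$cell_i[mine] == id, con$cell_j[mine],
                     con$cell_i[mine]),
    area = con$area[mine], prev_area = con$prev_area[mine],
    EBc = ifelse(con$cell_i[mine] == id, con$EBc_i[mine], con$EBc_j[mine])
  )
  new_cell(id, cells$x[idx], cells$y[idx], radius = cells$radius[idx],
           expression = cells$expression[idx], E = cells$E[idx],
           B = cells$B[idx], EB = cells$EB[idx], sites = sites,
           phase = cells$phase[idx])
}

put_cell <- function(world, idx, cell) {
  id <- world$cells$id[idx]
  world$cells$E[idx] <- cell$E
  world$cells$B[idx] <- cell$B
  world$cells$EB[idx] <- cell$EB
  for (r in seq_len(nrow(cell$sites))) {
    p <- cell$sites$partner[r]
    row <- which((world$contacts$cell_i == id & world$contacts$cell_j == p) |
                   (world$contacts$cell_j == id & world$contacts$cell_i == p))
    if (world$contacts$cell_i[row[1]] == id) {
      world$contacts$EBc_i[row[1]] <- cell$sites$EBc[r]
    } else {
      world$contacts$EBc_j[row[1]] <- cell$sites$EBc[r]
    }
  }
  world
}

# monolithic R reference of the engine loop for the two-cell scenario:
# bookkeeping -> pathway (all cells) -> mechanics, no cycle, no noise
reference_two_cell_run <- function(duration, dt = 0.01, variant = "model2",
                                   kin = kinetic_params(),
                                   mech = mech_params()) {
  d1 <- distance_for_contact_area(1, 5, 5)
  world <- build_world(data.frame(x = c(0, d1), y = c(0, 0)))
  n_steps <- round(duration / dt)
  for (k in seq_len(n_steps)) {
    world <- contact_bookkeeping(world)
    for (i in seq_len(nrow(world$cells))) {
      world <- put_cell(world, i,
                        step_pathway(world_cell(world, i), dt, variant, kin))
    }
    world <- motion_step(world, dt, variant, mech)
  }
  world
}

# separation force between cells 1 and 2 of a world via the bond map, nN
pair_force_nN <- function(world, variant = "model2") {
  con <- world$contacts
  if (!nrow(con)) return(0)
  m <- pmin(con$EBc_i[1], con$EBc_j[1])
  adhesion_force(if (variant == "model3") "model2" else variant, m, m) / 1000
}

# quick colony run helper
colony_run <- function(variant, rho_d, ci, days, seed = 1, ...) {
  run_colony(make_scenario("single_cell_colony", variant = variant,
    overrides = list(kinetic = kinetic_params(rho_d = rho_d),
                     contact_inhibition = ci, duration = days * 1440,
                     seed = seed, ...)))
}

# per-cell conservation residuals of a snapshot (E-cadherin and
# beta-catenin totals), using each cell's side of every contact row
conservation_residuals <- function(world) {
  cells <- world$cells
  con <- world$contacts
  bound <- vapply(cells$id, function(id) {
    sum(con$EBc_i[con$cell_i == id]) + sum(con$EBc_j[con$cell_j == id])
  }, numeric(1))
  cbind(E = cells$E + cells$EB + bound - cells$expression,
        B = cells$B + cells$EB + bound - 100)
}
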