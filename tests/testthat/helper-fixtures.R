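# shared fixture builders: small synthetic pipelines assembled in code

flat_params <- function(psi = 0.5, gamma = 0.12, eps = 0.39, p = 0.6,
                        n_forests = 1, n_years = 4) {
  occ_params(
    beta_psi = rep(0, 6),
    beta_gamma = rep(0, 1 + max(n_years - 2, 0)),
    beta_eps = rep(0, 1 + max(n_years - 2, 0)),
    beta_p = rep(0, 3 + max(n_years - 1, 0)),
    alpha_psi = rep(qlogis(psi), n_forests),
    alpha_gamma = rep(qlogis(gamma), n_forests),
    alpha_eps = rep(qlogis(eps), n_forests),
    alpha_p = rep(qlogis(p), n_forests),
    mu_psi = qlogis(psi), mu_gamma = qlogis(gamma),
    mu_eps = qlogis(eps), mu_p = qlogis(p)
  )
}

# a compact simulated pipeline: landscape -> fires -> z -> detections
small_pipeline <- function(n_cells = 60, n_forests = 3, years = 2021:2024,
                           params = NULL, seed = 1, fire_rate = 1,
                           p_skip = 0.1) {
  cells <- gen_landscape(n_cells, n_forests, seed = seed)
  burns <- gen_fire_history(cells, 1985:(max(years) - 1),
                            fire_rate = fire_rate, seed = seed + 1)
  if (is.null(params)) {
    params <- owl_preset(n_forests = n_forests, n_years = length(years),
                         seed = seed + 2)
  }
  st <- simulate_occupancy(cells, burns, params, years, seed = seed + 3)
  dep <- gen_deployments(cells, years, p_skip = p_skip, seed = seed + 4)
  det <- simulate_detections(st, dep, params, seed = seed + 5)
  list(cells = cells, burns = burns, params = params, st = st,
       dep = dep, det = det)
}

# hand-built one-cell deployment table
one_cell_deployment <- function(cell_id = "C0001", year = 2021,
                                start = "-04-01", nights = 126,
                                nightly_hours = 10, aru_id = "A1",
                                x = 0, y = 0) {
  s <- as.Date(paste0(year, start))
  data.frame(aru_id = aru_id, cell_id = cell_id, x = x, y = y,
             start_night = s, end_night = s + nights - 1,
             nightly_hours = nightly_hours, stringsAsFactors = FALSE)
}

pred_row <- function(cell_id = "C0001", aru_id = "A1",
                     night = as.Date("2021-04-05"), segment_start = 100,
                     call_type = "four-note", confidence = 0.99,
                     validated = "true-positive") {
  data.frame(cell_id = cell_id, aru_id = aru_id, night = night,
             segment_start = segment_start, call_type = call_type,
             confidence = confidence, validated = validated,
             stringsAsFactors = FALSE)
}
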