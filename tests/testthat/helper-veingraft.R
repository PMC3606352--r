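# Shared fixtures: all inputs are built in code.

default_params <- vg_params()

# Monte-Carlo oracle for the forward labeling model: an explicit population
# of cells under the model's assumptions (fraction p * Tc cycling with
# uniform phase, deterministic cycle, retrospective S-phase assignment,
# label inherited by both daughters). Independent of the closed form.
mc_label_fraction <- function(p, n_cells, params = default_params) {
  Tc <- params$cell_cycle
  lab_lo <- Tc / 3
  lab_hi <- 2 * Tc / 3 + params$brdu_window
  cycling <- stats::runif(n_cells) < p * Tc
  t_div <- stats::runif(n_cells, 0, Tc)
  labeled <- cycling & t_div >= lab_lo & t_div <= lab_hi
  divided <- cycling & t_div <= params$T_B
  100 * (2 * sum(labeled & divided) + sum(labeled & !divided)) /
    (n_cells + sum(divided))
}

# 1-D column grid with a given kind sequence (outer -> lumen)
make_column_grid <- function(kinds, element_size = 7) {
  g <- init_grid(1, mode = "single_smc_1d", element_size = element_size)
  g <- remove_element(g, 1, 1)
  for (k in kinds) g <- insert_element(g, 1, length(g$kind[[1]]) + 1L, vg_element(k))
  g
}

# n_columns-wide grid with given column height profile, all ECM
make_profile_grid <- function(heights, element_size = 7) {
  g <- init_grid(length(heights), mode = "mixed_layer_2d",
                 init_smc_fraction = 0.5, element_size = element_size, seed = 1)
  for (cc in seq_along(heights)) {
    while (length(g$kind[[cc]]) > 0) g <- remove_element(g, cc, 1)
    for (i in seq_len(heights[cc])) {
      g <- insert_element(g, cc, i, vg_element("ECM"))
    }
  }
  g
}

quiet <- function(expr) suppressWarnings(expr)
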