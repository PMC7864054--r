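# Shared fixtures built in code; kept small so the suite stays fast.

# A compact synthetic field: 12 cells on a 950 px square at the x60 pixel size.
small_field_spec <- function(seed = 101, n_cells = 12, ...) {
  field_spec(n_cells = n_cells, image_size = c(950, 950), seed = seed, ...)
}

# Disc painted into a logical matrix (r, c are the centre; radius in px).
paint_disc <- function(nr, nc, r0, c0, radius, value = TRUE,
                       into = matrix(FALSE, nr, nc)) {
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  hit <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  into[cbind(g$r[hit], g$c[hit])] <- value
  into
}

# Canonical generating parameter set for quench recovery studies.
canonical_quench <- function() {
  data.frame(well = "w1", G_CFTR = 1, V_M = -60, G_trans = 0.5,
             tau_trans = 5, f_mcherry_well = 1)
}

# Minimal two-genotype, imaging-only plate map.
two_well_map <- function() {
  data.frame(well = c("A1", "A2"), genotype = c("WT", "F508del"),
             role = "imaging", is_wt_reference = c(TRUE, FALSE),
             stringsAsFactors = FALSE)
}
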