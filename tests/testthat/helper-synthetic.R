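# Shared fixtures: small fields render in about a second each, so tests
# build what they need in code rather than caching binaries.

tiny_spec <- function(rows = 5, cols = 5, mold_D = 5, d = 10, h = 22,
                      s = 0.26, px = 0.25, z_step = 2) {
  array_spec(
    mold_diameter_um = mold_D, interpillar_um = d, height_um = h,
    swelling_fraction = s, rows = rows, cols = cols,
    pixel_size_um = px, z_step_um = z_step
  )
}

# Render a field and return the projections the measurement chain uses.
rendered_fixture <- function(spec, truth, noise = noise_model_none(),
                             seed = 11, base_z = 4) {
  rf <- render_field(spec, truth, noise, seed = seed)
  list(
    stack = rf$stack,
    truth = rf$truth,
    pillar = max_project(rf$stack, "PILLAR", 0, Inf),
    mbp = max_project(rf$stack, "MBP", base_z, Inf),
    nuclei = max_project(rf$stack, "NUCLEI", 0, Inf)
  )
}

# A field_truth built by hand (e.g. nuclei-only layouts for counting tests).
manual_truth <- function(pillars, nuclei, extent_um, myelin_z_lo_um = 4) {
  structure(
    list(
      pillars = pillars,
      nuclei = nuclei,
      extent_um = c(x = extent_um[1], y = extent_um[2]),
      margin_um = 0,
      myelin_z_lo_um = myelin_z_lo_um,
      seed = 0L
    ),
    class = "field_truth"
  )
}

empty_pillars <- function() {
  tibble::tibble(
    pillar_id = integer(0), row = integer(0), col = integer(0),
    x_um = numeric(0), y_um = numeric(0), coverage = numeric(0),
    thickness_um = numeric(0), arc_start_deg = numeric(0),
    split_arc = logical(0), present = logical(0)
  )
}
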