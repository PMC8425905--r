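# shared fixtures: built in code, no files

all_scenes <- c("pelvis", "chest_arms_up", "chest_one_arm_down",
                "chest_two_arms_down", "two_legs")

water_ellipse_spec <- function(semi_y_cm, semi_x_cm, table = NULL) {
  phantom_spec(list(phantom_body(c(20.48, 20.48), c(semi_y_cm, semi_x_cm),
                                 hu = 0)),
               table = table)
}

# independent Dw oracle: per-pixel summation of water-equivalent area,
# never via mean-HU * total-area
dw_pixel_oracle <- function(hu, mask, spacing_mm) {
  if (inherits(mask, "body_mask")) mask <- mask$mask
  a_px <- spacing_mm[1] * spacing_mm[2] / 100
  2 * sqrt(sum((hu[mask] / 1000 + 1) * a_px) / pi)
}

# small disc helper for hand-built scenes on plain HU grids
paint_disc <- function(hu, center_rc, radius_px, value) {
  idx <- which(
    outer((seq_len(nrow(hu)) - center_rc[1])^2,
          (seq_len(ncol(hu)) - center_rc[2])^2, `+`) <= radius_px^2)
  hu[idx] <- value
  hu
}
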