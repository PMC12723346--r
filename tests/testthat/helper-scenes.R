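# shared fixtures: small layouts and rendered scenes built in code

small_binary_spec <- function(f = 10, spacing = 200)
  grid_spec("binary", feature_size = f, spacing = spacing)

small_layout <- function(spec = small_binary_spec(), extent = c(600, 600))
  generate_grid(spec, extent)

# render a 3 x 3 code field with configurable camera parameters
render_field <- function(rotation = 0, blur = 0, noise = 0, pixel_size = 1,
                         polarity = "bright_features", seed = 1,
                         spec = small_binary_spec(), image = c(512, 512),
                         translation = c(235, 235)) {
  lay <- generate_grid(spec, c(600, 600))
  cam <- camera_model(pixel_size, image, rotation = rotation,
                      translation = translation, polarity = polarity,
                      blur_sigma = blur, noise_sigma = noise, seed = seed)
  list(layout = lay, camera = cam, img = render(lay, cam),
       gt = ground_truth(lay, cam))
}

# TRUE when every detection's coordinate matches the code genuinely at that
# image position (codes may be only partially visible and still correct)
all_detections_truthful <- function(det, layout, camera, tol_px = NULL) {
  if (!nrow(det)) return(TRUE)
  gt_all <- ground_truth(layout, camera, margin_px = -1e9)
  if (is.null(tol_px)) tol_px <- 4 * layout$spec$feature_size / camera$pixel_size
  ok <- vapply(seq_len(nrow(det)), function(i) {
    j <- which(gt_all$x_index == det$x_index[i] & gt_all$y_index == det$y_index[i])
    length(j) == 1 &&
      sqrt((gt_all$px_row[j] - det$px_row[i])^2 +
           (gt_all$px_col[j] - det$px_col[i])^2) <= tol_px
  }, logical(1))
  all(ok)
}
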