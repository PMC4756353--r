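# Small-frame generator parameters for fast module tests: a 128 x 128 voxel
# (30.7 um) frame holds one beam per direction and four nuclei.
small_params <- function(...) {
  args <- utils::modifyList(list(ny = 128L, nx = 128L, n_nuclei = 4L),
                            list(...))
  do.call(synth_params, args)
}

# bare stack builder for hand-made fixtures
make_stack <- function(arr, cal = calibration(), role = "factin") {
  channel_stack(arr, cal, role)
}

# rasterise a solid 2D disk into section z1 (1-based) of an array
add_disk <- function(arr, z1, cy_um, cx_um, r_um, cal, value) {
  d <- dim(arr)
  yc <- (seq_len(d[2]) - 0.5) * cal$dy
  xc <- (seq_len(d[3]) - 0.5) * cal$dx
  m <- outer((yc - cy_um)^2, (xc - cx_um)^2, "+") <= r_um^2
  sl <- arr[z1, , ]
  sl[m] <- value
  arr[z1, , ] <- sl
  arr
}

# rasterise a solid ellipsoid (physical semi-axes) into a (nz,ny,nx) array
add_ellipsoid_arr <- function(arr, centre_um, semi_um, cal, value) {
  d <- dim(arr)
  zc <- (seq_len(d[1]) - 0.5) * cal$dz
  yc <- (seq_len(d[2]) - 0.5) * cal$dy
  xc <- (seq_len(d[3]) - 0.5) * cal$dx
  for (z in which(abs(zc - centre_um[3]) <= semi_um[3])) {
    u0 <- ((zc[z] - centre_um[3]) / semi_um[3])^2
    m <- outer(((yc - centre_um[2]) / semi_um[2])^2,
               ((xc - centre_um[1]) / semi_um[1])^2, "+") + u0 <= 1
    sl <- arr[z, , ]
    sl[m] <- value
    arr[z, , ] <- sl
  }
  arr
}

# match detections (0-based voxel centroids) to true centres (um);
# returns c(recall, precision) pooled over the supplied tables
match_detections <- function(dets, truth_um, cal, tol_um = 8) {
  if (!nrow(dets) || !nrow(truth_um)) return(c(recall = 0, precision = 0))
  dx <- cbind(dets$x * cal$dx, dets$y * cal$dy, (dets$z + 0.5) * cal$dz)
  tu <- as.matrix(truth_um[, c("x_um", "y_um", "z_um")])
  hit_t <- vapply(seq_len(nrow(tu)), function(i)
    min(sqrt(rowSums(sweep(dx, 2, tu[i, ])^2))) <= tol_um, logical(1))
  hit_d <- vapply(seq_len(nrow(dx)), function(j)
    min(sqrt(rowSums(sweep(tu, 2, dx[j, ])^2))) <= tol_um, logical(1))
  c(recall = mean(hit_t), precision = mean(hit_d))
}
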