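# Shared fixtures: built in code, no stored data.

# circular-cap tumor record centered at a retinal point
cap_record <- function(ecc, theta, rho, eye_id = "E1", n = 72, ...) {
  ctr <- retinal_point(ecc, theta)
  list(perimeter = retinomap:::cap_boundary(ctr, rho, n = n),
       perimeter_canonical = retinomap:::cap_boundary(ctr, rho, n = n),
       eye_id = eye_id, centroid = NULL, ...)
}

# uniform random points on the 60-degree cap (uniform on the sphere surface)
runif_cap <- function(n, radius = 60) {
  u <- runif(n)
  ecc <- acos(1 - u * (1 - cos(radius * pi / 180))) * 180 / pi
  retinal_point(ecc, runif(n, 0, 360))
}

# closed-form cap area fraction within the 60-degree window
cap_fraction <- function(rho, radius = 60) {
  (1 - cos(rho * pi / 180)) / (1 - cos(radius * pi / 180))
}
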