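# Exact ideal geometries built in code; all distances in Angstrom.

fix_h3 <- function(r = 1) {
  a <- 2 * pi * (0:2) / 3
  molecule(rep("H", 3), cbind(r * cos(a), r * sin(a), 0))
}

fix_water <- function() {
  # C2v, principal axis z
  ang <- 104.5 / 2 * pi / 180
  d <- 0.9584
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(d * sin(ang), 0, -d * cos(ang)),
                 c(-d * sin(ang), 0, -d * cos(ang))))
}

fix_ammonia <- function() {
  a <- 2 * pi * (0:2) / 3
  molecule(c("N", "H", "H", "H"),
           rbind(c(0, 0, 0.38),
                 cbind(0.9377 * cos(a), 0.9377 * sin(a), 0)))
}

fix_methane <- function(d = 1.087) {
  s <- d / sqrt(3)
  molecule(c("C", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), s * rbind(c(1, 1, 1), c(1, -1, -1),
                                       c(-1, 1, -1), c(-1, -1, 1))))
}

fix_benzene <- function() {
  a <- 2 * pi * (0:5) / 6
  molecule(c(rep("C", 6), rep("H", 6)),
           rbind(cbind(1.39 * cos(a), 1.39 * sin(a), 0),
                 cbind(2.47 * cos(a), 2.47 * sin(a), 0)))
}

fix_ferrocene <- function() {
  # staggered (D5d) ferrocene
  a <- 2 * pi * (0:4) / 5
  b <- a + pi / 5
  molecule(c("Fe", rep("C", 10), rep("H", 10)),
           rbind(c(0, 0, 0),
                 cbind(1.22 * cos(a), 1.22 * sin(a), 1.66),
                 cbind(1.22 * cos(b), 1.22 * sin(b), -1.66),
                 cbind(2.29 * cos(a), 2.29 * sin(a), 1.635),
                 cbind(2.29 * cos(b), 2.29 * sin(b), -1.635)))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
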