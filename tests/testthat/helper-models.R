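# Small structure-model utilities for tests.

chain_coords_of <- function(model, chain = "A") {
  a <- model$atoms
  sel <- a[a$chain == chain & a$atom == "CA", ]
  as.matrix(sel[order(sel$resno), c("x", "y", "z")])
}

rotate_model <- function(model, theta) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% R
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
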