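# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_phantom <- function() fixture("default_phantom", function() {
  generate_phantom(phantom_spec())
})

default_case <- function() fixture("default_case", function() {
  ph <- default_phantom()
  list(ph = ph, res = run_case(ph$ap, ph$lat))
})

# the 50-phantom noiseless recovery batch shared by several tests
recovery_batch <- function() fixture("recovery_batch", function() {
  batch <- generate_batch(50, seed = 42)
  lapply(batch, function(ph) {
    res <- run_case(ph$ap, ph$lat)
    list(ph = ph, res = res)
  })
})

landmark_errors <- function(res, ph,
                            names = c("ST", "UBR", "UH", "ul_UBR", "DJ", "VJB")) {
  vapply(names, function(nm) {
    sqrt(sum((as.numeric(res$landmarks[[nm]]) -
                as.numeric(ph$truth$landmarks[[nm]]))^2))
  }, numeric(1))
}

param_errors <- function(res, ph) {
  tp <- ph$truth$params
  c(RA = res$params$RA - tp$RA, RL = res$params$RL - tp$RL,
    UV = res$params$UV - tp$UV, PT = res$params$PT - tp$PT)
}

# dense pixel-ring contour of a circle, for rotating-line oracles
circle_contour <- function(center = c(100, 100), r = 50, n = 720) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  new_contour(cbind(center[1] + r * cos(a), center[2] + r * sin(a)))
}
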