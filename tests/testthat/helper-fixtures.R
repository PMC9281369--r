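## Shared fixtures, built in code and memoized per test run.

.fx <- new.env(parent = emptyenv())

fixture_system <- function() {
  if (is.null(.fx$sys)) .fx$sys <- buildSyntheticSystem()
  .fx$sys
}

fixture_g4 <- function() {
  if (is.null(.fx$g4)) .fx$g4 <- buildIdealG4(3, channelIons = 2)
  .fx$g4
}

fixture_duplex <- function() {
  if (is.null(.fx$dx)) .fx$dx <- buildDuplexStem(3)
  .fx$dx
}

## a tiny model with named atoms at given coordinates
point_model <- function(xyz, names = NULL, resids = NULL, element = NULL) {
  n <- nrow(xyz)
  if (is.null(names)) names <- paste0("X", seq_len(n))
  if (is.null(resids)) resids <- seq_len(n)
  if (is.null(element)) element <- substr(names, 1, 1)
  StructureModel(data.frame(name = names, resid = resids,
                            resname = "X", element = element), xyz)
}

## trajectory from an explicit list of coordinate matrices
traj_from_frames <- function(model, frames, box = NULL) {
  arr <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  TrajectorySet(model, arr, box = box)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

## Ideal-gas RDF fixture: n_ions particles uniform in a cubic box around a
## fixed 3-atom solute at the origin.
ideal_gas_traj <- function(n_ions = 60, n_frames = 40, box = 70, seed = 19) {
  solute <- data.frame(name = c("O6", "O6B", "O6C"), resid = 1L,
                       resname = "G", element = "O")
  ions <- data.frame(name = "K", resid = 1L + seq_len(n_ions), resname = "K",
                     element = "K")
  xyz0 <- rbind(c(0.5, 0, 0), c(-0.5, 0.3, 0), c(0, -0.3, 0.4))
  model <- StructureModel(rbind(solute, ions),
                          rbind(xyz0, matrix(0, n_ions, 3)))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f)
    rbind(xyz0, matrix(runif(n_ions * 3, -box / 2, box / 2), n_ions, 3)))
  traj_from_frames(model, frames, box = matrix(box, n_frames, 3))
}

## Two-family trajectory: duplex atoms displaced by +d in family B,
## quadruplex identical across all frames.
two_blob_traj <- function(n_a = 6, n_b = 4, d = 3, seed = 9, noise = 0) {
  sys <- fixture_system()
  m <- sys$model
  dup_res <- sort(unique(as.vector(duplexPairs(sys$annotation))))
  dup_idx <- selectAtoms(m, sprintf("resid %d-%d", min(dup_res), max(dup_res)))
  set.seed(seed)
  frames <- list()
  labels <- integer(0)
  for (i in seq_len(n_a + n_b)) {
    xyz <- coords(m)
    if (i > n_a) xyz[dup_idx, ] <- xyz[dup_idx, ] +
        matrix(c(d, 0, 0), length(dup_idx), 3, byrow = TRUE)
    if (noise > 0) xyz <- xyz + matrix(rnorm(length(xyz), 0, noise),
                                       nrow(xyz), 3)
    frames[[i]] <- xyz
    labels[i] <- if (i > n_a) 2L else 1L
  }
  list(traj = traj_from_frames(m, frames), truth = labels,
       masks = list(g4 = "resid 1-12 and heavy",
                    duplex = sprintf("resid %d-%d and heavy",
                                     min(dup_res), max(dup_res))))
}
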