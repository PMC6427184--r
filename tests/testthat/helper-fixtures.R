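# Shared image fixtures, built once per test run.

fixture_env <- new.env()

fixture_image <- function(kind = "blobs", size = c(128, 128), seed = 7) {
  key <- paste(kind, paste(size, collapse = "x"), seed, sep = "_")
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- makeTextureImage(kind, size, seed)
  fixture_env[[key]]
}

rigid_true <- function() rigidToMatrix(rigidParams(10, -10, 5))

mild_projective <- function() {
  m <- rigidToMatrix(rigidParams(3, -6, 4))@matrix
  m[1, 3] <- 2e-4
  m[2, 3] <- -1e-4
  projectiveTransform(m)
}
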