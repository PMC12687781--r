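# Shared fixtures: small deterministic complexes and helpers. Everything is
# generated in code; no data files.

fixture_complex <- function(seed = 3L, rl = 20L, ll = 18L) {
  generate_bound_complex(toy_complex_spec(rl, ll, seed = seed))
}

# Apply one rigid transform (Q, v) to every chain of a complex.
transform_complex <- function(cx, Q, v) {
  cx$chains <- lapply(cx$chains, function(ch) {
    flowdock:::map_chain_coords(ch, function(p) {
      t(Q %*% t(p)) + matrix(v, nrow(p), 3, byrow = TRUE)
    })
  })
  cx
}

# Move only the ligand chain rigidly.
move_ligand <- function(cx, Q, v) {
  li <- cx$ligand_index
  cx$chains[[li]] <- flowdock:::map_chain_coords(cx$chains[[li]], function(p) {
    t(Q %*% t(p)) + matrix(v, nrow(p), 3, byrow = TRUE)
  })
  cx
}

random_rotation <- function(seed) {
  set.seed(seed)
  sample_uniform_rotation()
}

expect_rotation <- function(R, tol = 1e-8) {
  expect_lt(max(abs(crossprod(R) - diag(3))), tol)
  expect_lt(abs(det(R) - 1), tol)
}
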