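# Fixtures are built in code: no data files ship with the tests.

# Exact pressure-flow samples of the quadratic law dP = f*Q + s*Q^2.
quad_samples <- function(f, s, flows = 1:4, pa = 100) {
  tibble::tibble(
    flow_mls = as.numeric(flows),
    pa_mmhg = rep(pa, length(flows)),
    pd_mmhg = pa - (f * flows + s * flows^2)
  )
}

# D0 = 3 mm, L = 30 mm vessel with a mid-vessel 70% area stenosis.
ref_stenosed_vessel <- function(sa = 0.7, lesion_length = 10, n = 201) {
  seg <- make_straight_vessel(3, 30, n, segment_id = "ref")
  apply_stenosis(seg, stenosis_spec(15, lesion_length, sa))
}

# Short-lesion variant whose viscous integral stays close to the healthy
# tube's, so (f, s) ~ (0.396, 0.652) and SmartFFR ~ 0.957.
short_lesion_vessel <- function(sa = 0.7) {
  ref_stenosed_vessel(sa = sa, lesion_length = 1, n = 601)
}

# Symmetric bifurcation: healthy parent, two identically stenosed branches.
symmetric_tree <- function(sa = 0.5) {
  parent <- make_straight_vessel(3.5, 20, 101, segment_id = "LM")
  branch <- function(id) {
    seg <- make_straight_vessel(3, 30, 201, segment_id = id)
    apply_stenosis(seg, stenosis_spec(15, 10, sa))
  }
  coronary_tree(
    segments = list(LM = parent, LAD = branch("LAD"), LCx = branch("LCx")),
    root = "LM", children = list(LM = c("LAD", "LCx"))
  )
}

# Brute-force Mann-Whitney AUC with the package's orientation (low value =
# diseased): concordance of diseased-below-healthy pairs, ties count half.
brute_force_auc <- function(values, labels) {
  x <- values[labels == 1]
  y <- values[labels == 0]
  mean(outer(x, y, "<") + 0.5 * outer(x, y, "=="))
}

# Exhaustive Youden search mirroring the stated conventions: candidate
# thresholds are the observed values, positive means value <= t, ties broken
# by the largest maximising threshold.
brute_force_youden <- function(values, labels) {
  ts <- sort(unique(values))
  j <- vapply(ts, function(t) {
    mean(values[labels == 1] <= t) + mean(values[labels == 0] > t) - 1
  }, 0)
  list(cutoff = max(ts[j == max(j)]), j = max(j))
}
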