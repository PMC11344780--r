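## shared miniature cohort, built once per test run
.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_env$fx)) .fixture_env$fx <- make_fixture(42)
  .fixture_env$fx
}

## one joint trial log + steering series from the fixture
get_joint_trial <- function(pair = 1, which = 1) {
  fx <- get_fixture()
  joint <- Filter(function(tr) tr$mode == "joint",
                  fx$sessions[[pair]]$trials)
  joint[[which]]$logs[[1]]
}
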