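# Fixtures built in code.

# Hand-laid 6-subject counting-process panel: events at months 1, 2 (tied
# across two subjects) and 0, monotone treatments covering three exposure
# categories at the event, and non-trivial L/L0 values on a small scale.
tiny_panel <- function() {
  rows <- rbind(
    data.frame(id = 1, start = 0:2, event = c(0, 0, 1),
               a1 = c(0, 1, 1), a2 = c(0, 0, 1), L = c(6.0, 5.5, 4.8)),
    data.frame(id = 2, start = 0:1, event = c(0, 1),
               a1 = c(0, 0), a2 = c(1, 1), L = c(5.2, 5.0)),
    data.frame(id = 3, start = 0:3, event = 0,
               a1 = 1, a2 = 0, L = c(7.1, 7.0, 6.8, 6.9)),
    data.frame(id = 4, start = 0:2, event = c(0, 0, 1),
               a1 = c(0, 0, 1), a2 = c(0, 1, 1), L = c(6.4, 6.1, 5.2)),
    data.frame(id = 5, start = 0, event = 1, a1 = 0, a2 = 0, L = 4.1),
    data.frame(id = 6, start = 0:3, event = 0,
               a1 = c(0, 0, 0, 1), a2 = 0, L = c(6.6, 6.5, 6.2, 6.0)))
  rows$stop <- rows$start + 1
  first <- !duplicated(rows$id)
  rows$L0 <- rows$L[first][match(rows$id, rows$id[first])]
  as_long_panel(rows)
}

# deterministic positive row weights for the tiny panel
tiny_weights <- function(panel) 0.5 + (seq_len(nrow(panel)) %% 5) / 4

# tiny_panel plus two subjects so every exposure category carries an event:
# needed for fits that include the interaction term
tiny_panel8 <- function() {
  extra <- rbind(
    data.frame(id = 7, start = 0:1, event = c(0, 1),
               a1 = c(1, 1), a2 = c(0, 0), L = c(5.9, 5.6)),
    data.frame(id = 8, start = 0:2, event = 0,
               a1 = c(0, 1, 1), a2 = c(0, 0, 0), L = c(6.3, 6.1, 6.2)))
  extra$stop <- extra$start + 1
  first <- !duplicated(extra$id)
  extra$L0 <- extra$L[first][match(extra$id, extra$id[first])]
  base <- as.data.frame(tiny_panel())
  base$a2[base$id == 3] <- c(0, 1, 1, 1)  # surviving (1,1) person-time
  as_long_panel(rbind(base, extra))
}

quick_sim <- function(n = 400, seed = 1, scenario = "1A", ...) {
  simulate_dataset(scenario_config(scenario, n_subjects = n, seed = seed, ...))
}
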