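---
title: "The risk pooling game: model, metrics and synthetic experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The risk pooling game: model, metrics and synthetic experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`riskpool` simulates and analyses a two-player economic game in which paired
players manage a renewable resource under environmental volatility and can
pool risk by transferring resources to one another. The design mirrors
informal insurance arrangements documented among East African pastoralists,
in which *need-based* transfers (gifts on request, limited to the need,
creating no debt — the Maasai *osotua* institution) coexist with
*debt-based* transfers (loans expecting repayment in at least equal value —
*esile*). This vignette is the package's account of the model, the seven
behavioral variables, the statistical pipeline, and the design decisions
taken where the lab protocol leaves details open.

## Resource dynamics

Each player holds a stock $s \ge 0$ of a resource. Within a period a player
harvests $h$, receives growth, exchanges transfers and takes a shock, in
this order:

$$s' = s - h, \qquad
  s'' = s' + g(s'), \qquad
  s''' = \max(s'' + \text{received} - \text{given} + \epsilon,\ 0).$$

The natural growth rule is the cubic strong-Allee form

$$g(s) = r\, s \left(\frac{s}{L} - 1\right)\left(1 - \frac{s}{U}\right),$$

with rate $r$ and lower/upper critical values $L < U$: stocks shrink below
$L$ and above $U$ and grow in between. Two regimes are used: **high
volatility** ($r = 0.25$, $L = 8$, $U = 25$) and **low volatility**
($r = 0.05$, $L = 2$, $U = 25$). The argmax of $g$ is
$(U + L + \sqrt{U^2 - UL + L^2})/3$: 18.37 units under high and 17.02 under
low volatility, which is exactly the in-game advice to players to hold
their stock near 18 or 17 units. The cubic is a design decision — the
published protocol specifies only the parameters, the critical values, the
sign pattern and the optima — and it is the *minimal* smooth form
consistent with all of those facts; the regime object is a plugin, so an
alternative rule can be substituted.

Growth acts on the post-harvest stock (the one ordering constraint the
protocol states); transfers and the shock apply after growth, so a donor's
capacity to give is their post-growth stock. Stocks are real-valued by
default (`integer_stocks` rounds them; granularity is unstated in the
protocol).

Shocks average zero, can be positive or negative, and are independent of
stock size. The default model is normal with sd `scale`; uniform and
discrete-uniform alternatives are provided since the lab distribution is
unpublished. Stocks are floored at zero after the shock.

## Session structure, survival and earnings

A session is a 7-period practice block plus four rounds of twenty periods,
half high- and half low-volatility, order counterbalanced across sessions.
At every round start stocks reset to `initial_stock` (default 15, inside
the growth-positive band of both regimes), ledgers clear, and partners are
reassigned — a round-robin rotation over a shuffled ordering, so every
player faces four distinct partners. A player whose stock stays below the
survival threshold for three consecutive periods is out of the round:
unable to harvest, request, or respond. The threshold itself is not
published; the default is the active regime's lower critical value $L$,
the stated boundary below which stocks begin to shrink, and it is
configurable. Players earn a \$5 show-up fee plus \$1 per 15 units
harvested.

Practice periods are simulated (recorded as `round = 0`) but excluded from
metrics and earnings by default: they exist so the synthetic pipeline has
the same shape as the lab data, warts included.

## Transfer policies

Four decision policies map an observation (own stock, partner's stock —
holdings are mutually visible — the pairing's transfer ledger, and any
pending request) to harvest, request and give actions:

* **need-based**: request only when stock falls below `need_threshold`
  (default 8), and only the top-up to `safe_level` (default 12); answer
  requests with anything above `safe_level`; ignore the ledger entirely.
* **debt-based**: as need-based, but refuse to give while the asker's debt
  is open, refuse to ask while one's own debt is open, and repay
  `min(debt, surplus)` unprompted when holding a surplus. Repayment is
  exact-amount; over-repayment is a parameter left at zero.
* **none**: never request, never give.
* **stochastic**: the human-like blend used by the synthetic generator —
  need-based decisions emitted with probabilities `ask_propensity` and
  `give_propensity`, and suppressed with probability `debt_sensitivity`
  when a debt is open. At (`1`, `1`, `0`) it reduces exactly to the
  need-based rule; `debt_sensitivity = 1` makes repetitive asking and
  giving structurally impossible.

All policies share the same harvest rule — skim whatever exceeds the
regime's growth optimum — so survival differences between pairings isolate
the transfer rules, not harvesting skill. How human players actually
balanced harvesting against giving capacity is unobservable from the
published protocol; the shared rule is a documented assumption, not a claim
about the lab.

"Repaid" is operationalised on the *net* ledger of the current pairing
(given minus received; a debt is open while the balance is nonzero in the
relevant direction, exact zero counts as repaid). Net accounting is the
simplest auditable rule consistent with defining repetitive asking/giving
by "had not yet repaid". A gift-by-gift variant — each transfer first
repays the giver's own open debt, and *over*-repayment closes the debt
without creating a reverse one, as a repayment "at least as valuable"
should — is implemented as `accounting = "gift"`; the two conventions
agree whenever gifts are repaid in full or not at all, and both are
reported by the analysis scripts.

## The seven behavioral variables

Per player, over all scored play: repetitive giving (periods giving across
the partner's open debt), repetitive asking (asking across one's own open
debt), mean amounts requested and given (averaged over the periods the
player was in the game, zeros included; a per-event variant sits behind
`per_event = TRUE`), number of requests made, number of requests answered
positively (the responder's count), and matching — the absolute difference
between totals given and received, where *small* values indicate
tit-for-tat balance and *large* values tolerance of one-way flows. Periods
survived (of 80) is carried alongside. The per-period denominator counts
periods the player was alive in-game; the averaged-over-all-play reading
of the variable definitions is ambiguous between per-period and per-event,
so both are implemented and the per-period form is the default.

## Statistics

Group comparisons are independent-samples t tests, Student's
pooled-variance form by default with Welch behind a flag (reports include
both), two-tailed uniformly. Cohen's d uses the pooled SD with $n-1$
weights, signed so that positive means the primed group scored higher
(negative t, with control passed first). With seven comparisons the
Bonferroni-adjusted alpha is $0.05/7$, reported as 0.007. Before pooling
the four primed sub-conditions, a one-way ANOVA per variable with Scheffé
pairwise contrasts checks for sub-condition differences. The t tests and
ANOVA are delegated to `stats::t.test()` and `stats::aov()`; Cohen's d and
the Scheffé contrasts are computed directly from the textbook formulas
(cross-checked in the tests against the pooled identity
$t = -d\sqrt{n_1 n_2/(n_1+n_2)}$ and `aov`'s mean squares). The headline
unit of analysis is one row per player pooled over all four rounds.

## The synthetic generator

`generate_experiment()` stands in for the human sessions: 40 control and
158 primed players (the primed side optionally labelled with its four
sub-conditions, sized 40/40/40/38), each drawing individual propensities
from truncated normals (sd 0.15, clipped to $[0,1]$) around group means,
playing in two counterbalanced sessions per group. Primed players default
to higher `give_propensity` and lower `debt_sensitivity` — the direction
of the experimental findings; the generator *plants* effects, it does not
model priming psychology.

The generator's game uses shock sd 4 (`lab_game_config()`), chosen against
the one quantitative anchor the experiment reports about its environment:
slightly more than half of players survived all eighty periods. At sd 2
essentially nobody dies and need never arises; at sd 4 the simulated
full-survival fraction sits just above one half and players make a handful
of requests per session. This is a choice of emulated conditions, fixed
once; the engine default elsewhere remains sd 2.

`calibrate_to_effect_sizes()` tunes a single *disposition gap* $g$ —
give-propensities split by $g$, debt-sensitivities by $-g$, and
ask-propensities by $g/4$, since asking responded much less to priming
than giving did — over a coarse grid with one refinement, each point
scored on fixed-seed replicate batches (common random numbers across
gaps). Targets outside reach are reported with a warning, never clipped.
With targets $d = 0.65$ (mean amount given) and $d = 0.46$ (repetitive
giving) the calibrated gap lands near 0.4–0.45, and the *other five*
variables then fall close to their reported effect sizes without being
targeted — the game dynamics, not the knob, set their relative magnitudes.

What the generator does *not* emulate: learning across rounds, framing
differences among sub-conditions, harvest-strategy heterogeneity, and any
psychology behind the propensities. Passing tests therefore show that the
pipeline recovers planted effects of the reported size and direction at
the reported sample sizes — not that the mechanism generating human
behavior is the one simulated.

## Numerical choices and degenerate inputs

Ledger comparisons use a $10^{-9}$ tolerance; "repaid" ties break to
repaid at exactly zero. Zero-variance groups with equal means return
$t = 0, p = 1$ (a well-defined null); with unequal means they raise an
error rather than emitting NaN. Players with zero periods of play make
per-period means undefined and raise an error. Dead players are frozen —
no growth, shocks or actions — and their rows remain in the log with
`alive_post = FALSE`. All randomness flows from a single seed per entry
point; identical seeds give byte-identical logs and reports.

Problem sizes in the shipped tests and acceptance script — e.g. 500
sessions per strategy pairing, 50–100 replicate experiments for
calibration checks, 1000 random logs against the replay oracle — were
chosen as the smallest runs whose Monte-Carlo error is comfortably below
the effects being checked.

## Interfaces

CSV is the native interchange (session logs and metrics tables carry a
provenance comment header with the producing step, seed and config hash);
configurations serialise to YAML. External tables — in particular the
experiment's deposited spreadsheet, whose internal schema is unpublished —
are imported via a `column_mapping()` that must map every mandatory field
exactly once, after export to CSV; the mapping object is the documented
contract for whatever that file contains. The numbered scripts under
`analysis/` are the workflow surface: simulate, metrics, comparison, the
strategy-pairing experiment, and effect-size calibration.

## Known limitations

Players who share a session interact, so their metrics are not fully
independent; the t tests treat them as if they were (as the original
analysis did), which leaves the seven-test family's empirical type-I rate
slightly above nominal in the null-generator calibration. Beyond the
generator's scope above: the growth rule's exact lab form,
shock distribution, survival threshold and initial stock are unpublished
and configurable rather than known; partner choice, multi-partner
networks and cheater detection are out of scope; and the deposited
participant data are not bundled, so the reproduction path is exercised
end-to-end on synthetic stand-ins and on any export of that file a user
supplies with a mapping.
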