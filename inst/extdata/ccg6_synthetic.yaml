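# SYNTHETIC constant-size centipede game, 6 steps.
# Not an empirical table: an equal split of a unit resource at step 1 and a
# taker share growing by 0.05 per step, with the pass-through favouring
# Player 1 at 80%. Serves as a stand-in for user-supplied constant-size
# schedules (e.g. transcribed from published experiments).
variant: constant-size
schedule:
  - [0.50, 0.50]   # step 1, Player 1 takes
  - [0.45, 0.55]   # step 2, Player 2 takes
  - [0.60, 0.40]
  - [0.35, 0.65]
  - [0.70, 0.30]
  - [0.25, 0.75]
pass_through: [0.80, 0.20]
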