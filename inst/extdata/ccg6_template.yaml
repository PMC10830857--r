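# Template for a user-supplied constant-size centipede game (6 steps).
# Fill each schedule row with the (Player 1, Player 2) payoffs when the
# game ends at that step (the seat owner takes: Player 1 at odd steps,
# Player 2 at even steps), and pass_through with the final split proposed
# when Player 2 postpones at the last step. Every row and the pass-through
# must sum to the same constant resource.
variant: constant-size
schedule:
  - ~   # step 1: [p1, p2]
  - ~   # step 2
  - ~   # step 3
  - ~   # step 4
  - ~   # step 5
  - ~   # step 6
pass_through: ~
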