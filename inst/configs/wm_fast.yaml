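# Desk-scale working-memory profile: one trial in about a minute on one CPU.
task: wm
N: 32
n_batch: 8
L_train: 1000
transient_train: 500
L_eval: 2000
transient_eval: 1000
n_eval: 8
lambda_I: 0.15
lambda_reg: 0.0001
mm_iterations: 800
sm_pretrain: 100
sm_per_mm: 20
lr_mm: 0.002
lr_sm: 0.002
sm_hidden: [64, 64]
sm_minibatch: 512
mi_minibatch: 4000
sigma_noise: 0.1
eval_every: 20
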