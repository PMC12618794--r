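# Desk-scale chaotic-separation profile (shortened; ordering contrasts only).
task: sep
N: 32
n_batch: 4
L_train: 300
L_eval: 300
n_eval: 4
lambda_I: 0.1
lambda_reg: 0.0001
mm_iterations: 120
sm_pretrain: 100
sm_per_mm: 20
lr_mm: 0.003
lr_sm: 0.002
sm_hidden: [64, 64]
sm_minibatch: 256
sigma_noise: 0.1
eval_every: 10
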