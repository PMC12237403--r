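reporter,replicate,cell_line,group,t_intra_min,y0,adj_r2,printed_dlq_dt,printed_v_nm_per_min,printed_dlq_decimals,printed_group_label
SBP-GFP-CD59,1,293T,SBP-GFP-CD59 (293T),0.74,0.66,0.94,0.244,66.7,3,5±4
SBP-GFP-CD59,2,293T,SBP-GFP-CD59 (293T),7.3,0.63,0.92,0.022,6.0,3,5±4
SBP-GFP-CD59,3,293T,SBP-GFP-CD59 (293T),6.8,0.79,0.85,0.040,10.9,3,5±4
TNFa-SBP-GFP,1,HeLa,TNFa-SBP-GFP,6.4,1.09,0.94,0.075,20.5,3,6.4
TfR-SBP-GFP,1,HeLa,TfR-SBP-GFP,7.0,1.16,0.99,0.075,20.6,3,7
SBP-GFP-CD8a-furin-Y+AC,1,HeLa,SBP-GFP-CD8a-furin-Y+AC,4.9,0.83,0.99,0.061,16.7,3,7±1
SBP-GFP-CD8a-furin-Y+AC,2,HeLa,SBP-GFP-CD8a-furin-Y+AC,7.1,1.00,0.99,0.059,16.0,3,7±1
SBP-GFP-CD8a-furin-Y+AC,3,HeLa,SBP-GFP-CD8a-furin-Y+AC,7.7,1.04,0.92,0.058,15.8,3,7±1
SBP-GFP-Tac,1,HeLa,SBP-GFP-Tac,6.0,0.86,0.98,0.053,14.6,3,7±2
SBP-GFP-Tac,2,HeLa,SBP-GFP-Tac,8.2,0.91,0.98,0.043,11.8,3,7±2
SBP-GFP-E-cadherin,1,HeLa,SBP-GFP-E-cadherin,7.6,0.98,0.99,0.053,14.5,3,8±1
SBP-GFP-E-cadherin,2,HeLa,SBP-GFP-E-cadherin,8.7,1.15,0.96,0.060,16.5,3,8±1
SBP-GFP-E-cadherin,3,HeLa,SBP-GFP-E-cadherin,6.5,1.11,0.98,0.075,20.6,3,8±1
SBP-GFP-collagenX,1,HeLa,SBP-GFP-collagenX,9.0,1.00,0.94,0.046,12.7,3,8±1
SBP-GFP-collagenX,2,HeLa,SBP-GFP-collagenX,9.5,0.84,0.97,0.032,8.8,3,8±1
SBP-GFP-collagenX,3,HeLa,SBP-GFP-collagenX,6.9,0.91,0.97,0.051,14.0,3,8±1
SBP-GFP,1,HeLa,SBP-GFP,10.6,0.74,0.98,0.022,6.1,3,10.6
SBP-GFP-CD8a-furin-YA,1,HeLa,SBP-GFP-CD8a-furin-YA,5.9,1.49,0.98,0.13,35.0,2,11±5
SBP-GFP-CD8a-furin-YA,2,HeLa,SBP-GFP-CD8a-furin-YA,11.1,1.51,0.93,0.069,19.0,3,11±5
SBP-GFP-CD8a-furin-YA,3,HeLa,SBP-GFP-CD8a-furin-YA,16.3,1.48,0.95,0.046,12.6,3,11±5
SBP-GFP-CD59,1,HeLa,SBP-GFP-CD59,13.0,1.03,0.97,0.034,9.2,3,13.0
SBP-GFP-Tac-TC,1,293T,SBP-GFP-Tac-TC (293T),14.7,0.95,0.97,0.026,7.1,3,14.2±0.6
SBP-GFP-Tac-TC,2,293T,SBP-GFP-Tac-TC (293T),14.3,1.00,0.98,0.029,8.0,3,14.2±0.6
SBP-GFP-Tac-TC,3,293T,SBP-GFP-Tac-TC (293T),13.6,0.98,0.89,0.030,8.1,3,14.2±0.6
SBP-GFP-Tac-TC,1,HeLa,SBP-GFP-Tac-TC,15.5,1.05,0.97,0.029,8.0,3,17±3
SBP-GFP-Tac-TC,2,HeLa,SBP-GFP-Tac-TC,19.1,1.16,0.94,0.028,7.6,3,17±3
SBP-GFP-CD8a-furin-WT,1,HeLa,SBP-GFP-CD8a-furin-WT,23.6,1.63,0.96,0.036,9.9,3,18±5
SBP-GFP-CD8a-furin-WT,2,HeLa,SBP-GFP-CD8a-furin-WT,18.7,1.58,0.97,0.044,12.0,3,18±5
SBP-GFP-CD8a-furin-WT,3,HeLa,SBP-GFP-CD8a-furin-WT,13.1,1.55,0.97,0.061,16.7,3,18±5
SBP-GFP-CD8a-furin-AC,1,HeLa,SBP-GFP-CD8a-furin-AC,17.9,1.73,0.99,0.052,14.1,3,21±5
SBP-GFP-CD8a-furin-AC,2,HeLa,SBP-GFP-CD8a-furin-AC,26.9,1.50,1.00,0.028,7.8,3,21±5
SBP-GFP-CD8a-furin-AC,3,HeLa,SBP-GFP-CD8a-furin-AC,23.2,1.58,0.96,0.035,9.7,3,21±5
SBP-GFP-CD8a-furin-AC,4,HeLa,SBP-GFP-CD8a-furin-AC,16.8,1.62,0.99,0.050,13.8,3,21±5
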