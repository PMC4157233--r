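electrons,asp_proton,prop_proton,e_reduced_cluster,e_oxidized_cluster,fes_potential,sub_potential_reduced,sub_potential_oxidized,sub_potential_no_cluster
0,Asp274,Propionate,0.00,0.00,2.70,2.78,2.81,2.92
0,Asp274,C18,20.34,19.98,2.69,3.90,3.91,4.06
0,C17,Propionate,25.36,25.25,2.70,3.95,3.97,4.15
1,Asp274,Propionate,-64.05,-64.70,2.67,NA,NA,2.33
1,Asp274,C18,-69.64,-70.17,2.68,2.47,2.49,2.81
1,C17,Propionate,-65.73,-66.24,2.68,2.83,2.85,3.11
1,C17,C18,-72.20,-72.14,2.70,4.22,4.25,4.49
2,Asp274,C18,-126.58,-127.57,2.66,NA,NA,NA
2,C17,Propionate,-131.10,-132.04,2.66,NA,NA,NA
2,C17,C18,-169.60,-170.10,2.68,NA,NA,NA
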