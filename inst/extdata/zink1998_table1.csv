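intensity_mA,polarity,measure,mean_deg,sd_deg,min_deg,max_deg,n
1.0,left_anodal,ocular_torsion,1.0,0.4,0.5,1.5,6
1.0,right_anodal,ocular_torsion,1.2,0.3,0.6,1.4,6
1.5,left_anodal,ocular_torsion,1.3,0.1,1.2,1.4,2
1.5,right_anodal,ocular_torsion,1.4,0.1,1.3,1.4,2
1.5,left_anodal,visual_tilt,2.2,0.9,1.3,3.3,4
1.5,right_anodal,visual_tilt,1.7,0.5,1.3,2.3,4
2.0,left_anodal,ocular_torsion,2.0,0.5,1.3,2.5,7
2.0,right_anodal,ocular_torsion,2.1,0.5,1.5,2.8,7
2.0,left_anodal,visual_tilt,2.6,1.4,1.3,6.3,12
2.0,right_anodal,visual_tilt,2.6,1.2,1.0,5.8,12
2.5,left_anodal,visual_tilt,3.2,2.3,1.2,9.4,12
2.5,right_anodal,visual_tilt,3.1,2.0,1.0,8.5,12
3.0,left_anodal,ocular_torsion,2.5,0.8,1.4,3.5,7
3.0,right_anodal,ocular_torsion,3.0,0.6,2.2,3.5,7
3.0,left_anodal,visual_tilt,4.9,1.5,3.0,6.5,4
3.0,right_anodal,visual_tilt,4.8,1.8,2.6,6.4,4
4.0,left_anodal,ocular_torsion,2.9,1.0,1.2,3.8,6
4.0,right_anodal,ocular_torsion,3.3,1.3,1.3,4.2,6
5.0,left_anodal,ocular_torsion,3.2,1.1,2.0,4.1,3
5.0,right_anodal,ocular_torsion,3.6,1.9,1.5,4.3,3
6.0,left_anodal,ocular_torsion,3.6,1.3,2.2,4.5,3
6.0,right_anodal,ocular_torsion,4.1,1.7,2.2,5.2,3
7.0,left_anodal,ocular_torsion,3.9,1.8,2.6,5.2,2
7.0,right_anodal,ocular_torsion,4.0,2.1,2.5,5.4,2
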