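participant,object,phase,success_rate_pct,response_time_ms
1,coffee_mug,pre,42,723
1,coffee_mug,post,91,530
1,wine_glass,pre,65,478
1,wine_glass,post,89,423
1,tennis_ball,pre,51,792
1,tennis_ball,post,68,697
2,coffee_mug,pre,50,528
2,coffee_mug,post,100,532
2,wine_glass,pre,54,780
2,wine_glass,post,62,702
2,tennis_ball,pre,33,771
2,tennis_ball,post,100,421
3,coffee_mug,pre,42,845
3,coffee_mug,post,64,811
3,wine_glass,pre,70,845
3,wine_glass,post,75,771
3,tennis_ball,pre,61,794
3,tennis_ball,post,73,805
4,coffee_mug,pre,54,576
4,coffee_mug,post,85,490
4,wine_glass,pre,50,786
4,wine_glass,post,55,515
4,tennis_ball,pre,66,784
4,tennis_ball,post,80,725
5,coffee_mug,pre,66,823
5,coffee_mug,post,78,783
5,wine_glass,pre,72,806
5,wine_glass,post,92,588
5,tennis_ball,pre,56,760
5,tennis_ball,post,72,722
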