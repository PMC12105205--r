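"ga_weeks","hc_mean_mm","hc_sd_mm","bpd_mean_mm","bpd_sd_mm"
14,98,2.94,27.2347767888287,0.817043303664861
15,105.6,3.168,29.3468615193909,0.880405845581727
16,113.2,3.396,31.4589462499531,0.943768387498594
17,120.8,3.624,33.5710309805154,1.00713092941546
18,128.4,3.852,35.6831157110776,1.07049347133233
19,136,4.08,37.7952004416398,1.13385601324919
20,143.6,4.308,39.907285172202,1.19721855516606
21,151.2,4.536,42.0193699027643,1.26058109708293
22,158.8,4.764,44.1314546333265,1.32394363899979
23,166.4,4.992,46.2435393638887,1.38730618091666
24,174,5.22,48.3556240944509,1.45066872283353
25,181.6,5.448,50.4677088250132,1.51403126475039
26,189.2,5.676,52.5797935555754,1.57739380666726
27,196.8,5.904,54.6918782861376,1.64075634858413
28,204.4,6.132,56.8039630166998,1.70411889050099
29,212,6.36,58.9160477472621,1.76748143241786
30,219.6,6.588,61.0281324778243,1.83084397433473
31,227.2,6.816,63.1402172083865,1.89420651625159
32,234.8,7.044,65.2523019389487,1.95756905816846
33,242.4,7.272,67.364386669511,2.02093160008533
34,250,7.5,69.4764714000732,2.0842941420022
35,257.6,7.728,71.5885561306354,2.14765668391906
36,265.2,7.956,73.7006408611976,2.21101922583593
37,272.8,8.184,75.8127255917598,2.2743817677528
38,280.4,8.412,77.9248103223221,2.33774430966966
39,288,8.64,80.0368950528843,2.40110685158653
40,295.6,8.868,82.1489797834465,2.4644693935034
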