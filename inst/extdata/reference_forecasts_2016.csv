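year,month,point_class1,point_class2,point_class3,point_class4,point_class5,se_class1,se_class2,se_class3,se_class4,se_class5
2016,1,206000,366000,589000,753000,1196000,9000,14000,21000,27000,58000
2016,2,210000,382000,609000,783000,1218000,11000,16000,24000,30000,64000
2016,3,208000,372000,582000,738000,1224000,11000,18000,28000,33000,76000
2016,4,210000,366000,582000,765000,1227000,12000,20000,31000,36000,83000
2016,5,195000,350000,546000,704000,1156000,14000,22000,34000,39000,91000
2016,6,194000,355000,544000,725000,1149000,14000,24000,37000,41000,98000
2016,7,204000,349000,530000,727000,1108000,15000,26000,40000,43000,105000
2016,8,197000,347000,527000,710000,1069000,16000,27000,42000,46000,111000
2016,9,196000,336000,511000,701000,1032000,17000,28000,45000,48000,117000
2016,10,206000,357000,552000,737000,1122000,18000,30000,47000,50000,123000
2016,11,214000,382000,593000,788000,1205000,18000,31000,49000,52000,128000
2016,12,222000,401000,594000,814000,1202000,19000,32000,51000,54000,133000
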